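#' Cold-allodynia withdrawal frequency
#'
#' Score of one acetone-test session: the number of hind-paw withdrawals over
#' the five acetone applications (one every 3 minutes). A fully insensitive
#' animal (the sham outcome) scores 0; a maximally sensitive one scores 5.
#'
#' @param trials integer/logical vector of exactly five 0/1 withdrawal
#'   indicators.
#' @return withdrawal count, 0-5.
#' @export
allodynia_score <- function(trials) {
  trials <- as.numeric(trials)
  if (length(trials) != 5L)
    stop_input("an acetone session has exactly 5 trials (got %d)",
               length(trials))
  if (!all(trials %in% c(0, 1)))
    stop_input("withdrawal indicators must be binary 0/1")
  sum(trials)
}

#' Elevated-plus-maze occupancy and entry metrics
#'
#' Scores one 300-s EPM session from an annotated zone-entry event table
#' (the all-four-paws entry criterion is assumed applied by the upstream
#' annotator). Zone times come from consecutive event differences with the
#' last zone held to the end of the session; entries count transitions into
#' each arm; `pct_closed` uses the full session length as denominator.
#'
#' @param events data frame with columns `time_s` (strictly increasing,
#'   first row `0`) and `zone` (`OPEN`, `CLOSED`, `CENTER`; first row
#'   `CENTER`, where the animal is placed).
#' @param session_length seconds (default 300, the five-minute session).
#' @return named vector: `open_time_s`, `closed_time_s`, `center_time_s`,
#'   `open_entries`, `closed_entries`, `pct_closed`.
#' @export
epm_metrics <- function(events, session_length = 300) {
  if (!all(c("time_s", "zone") %in% names(events)))
    stop_input("events must have columns time_s and zone")
  t <- as.numeric(events$time_s)
  z <- as.character(events$zone)
  if (length(t) == 0L) stop_input("empty EPM event table")
  if (!all(z %in% c("OPEN", "CLOSED", "CENTER")))
    stop_input("zones must be OPEN, CLOSED or CENTER")
  if (t[1L] != 0 || z[1L] != "CENTER")
    stop_input("session must start at (0, CENTER): animals are placed at the maze center")
  if (any(diff(t) <= 0)) stop_input("timestamps must be strictly increasing")
  if (any(t < 0) || any(t > session_length))
    stop_input("timestamps must lie within [0, %g] s", session_length)
  dwell <- diff(c(t, session_length))
  times <- vapply(c("OPEN", "CLOSED", "CENTER"),
                  function(zz) sum(dwell[z == zz]), numeric(1))
  entries <- function(zz)
    if (length(z) > 1L) sum(z[-1L] == zz & z[-length(z)] != zz) else 0L
  c(open_time_s = unname(times["OPEN"]),
    closed_time_s = unname(times["CLOSED"]),
    center_time_s = unname(times["CENTER"]),
    open_entries = entries("OPEN"),
    closed_entries = entries("CLOSED"),
    pct_closed = unname(100 * times["CLOSED"] / session_length))
}

#' Score a simulated behaviour table
#'
#' Applies [allodynia_score()] and [epm_metrics()] per animal.
#'
#' @param tab a `behavior_table` from [simulate_behavior()].
#' @return data frame with one row per animal: `animal_id`, `day`,
#'   `withdrawals`, and the EPM metrics.
#' @export
score_behavior <- function(tab) {
  stopifnot(inherits(tab, "behavior_table"))
  ids <- unique(tab$acetone$animal_id)
  do.call(rbind, lapply(ids, function(id) {
    ac <- tab$acetone[tab$acetone$animal_id == id, ]
    ep <- tab$epm[tab$epm$animal_id == id, ]
    m <- epm_metrics(ep)
    data.frame(animal_id = id, day = ac$day[1L],
               withdrawals = allodynia_score(ac$withdrawal),
               t(m))
  }))
}
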