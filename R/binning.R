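#' Phase-bin index of a pulse-to-target SOA
#'
#' Maps a pulse-to-target SOA onto one of the `period / width` half-open
#' phase bins `[k*width, (k+1)*width)`. With the 100-ms pulse period and
#' 10-ms bins there are exactly ten bins, indexed 0-9.
#'
#' @param pulse_soa SOA(s) in `[0, period)`.
#' @param width bin width (ms); must divide `period`.
#' @param period pulse period (ms).
#' @return Integer bin indices in `0 ... period/width - 1`.
#' @export
#' @examples
#' bin_index(c(0, 50, 99.9)) # 0 5 9
bin_index <- function(pulse_soa, width = 10, period = 100) {
  check_pos(width, "width")
  check_pos(period, "period")
  n_bins <- period / width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    abort_invalid("`width` must divide `period`", field = "width")
  if (any(pulse_soa < 0 | pulse_soa >= period))
    abort_invalid(sprintf("`pulse_soa` must lie in [0, %g)", period),
                  field = "pulse_soa")
  pmin(as.integer(floor(pulse_soa / width)), as.integer(round(n_bins)) - 1L)
}

#' Detection rates per 10-ms phase bin
#'
#' Converts a trial table into the analysis's basic unit: per participant
#' and condition, the proportion of targets detected in each of the
#' `period / width` pulse-to-target SOA bins. Catch trials (no target) and
#' trials without a valid response are excluded before computing
#' `rate_b = hits_b / (hits_b + misses_b)`; bins that receive no scored
#' trial carry `NA` with count 0.
#'
#' @param trials trial `data.frame` (needs `participant_id`, `condition`,
#'   `pulse_soa`, `catch`, `response`).
#' @param width,period bin width and pulse period (ms).
#' @return A long `data.frame` of class `binned_rates` with columns
#'   `participant_id`, `condition`, `bin` (0-based), `rate`, `count`.
#' @export
detection_rates <- function(trials, width = 10, period = 100) {
  bad <- setdiff(unique(trials$condition), c("sham", "otcs"))
  if (length(bad))
    abort_invalid(paste("unknown condition labels:", paste(bad, collapse = ", ")),
                  field = "condition")
  scored <- trials[!trials$catch & trials$response %in% c("hit", "miss"), ]
  n_bins <- as.integer(round(period / width))
  scored$bin <- bin_index(scored$pulse_soa, width, period)

  cells <- expand.grid(bin = 0:(n_bins - 1L),
                       condition = unique(trials$condition),
                       participant_id = unique(trials$participant_id),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$participant_id, d$condition, d$bin, sep = "\r")
  hits <- tapply(scored$response == "hit", key(scored), sum)
  tot <- tapply(scored$response == "hit", key(scored), length)
  idx <- match(key(cells), names(tot))
  cells$count <- ifelse(is.na(idx), 0L, as.integer(tot[idx]))
  cells$rate <- ifelse(cells$count > 0, as.numeric(hits[idx]) / cells$count,
                       NA_real_)
  out <- cells[order(cells$participant_id, cells$condition, cells$bin),
               c("participant_id", "condition", "bin", "rate", "count")]
  rownames(out) <- NULL
  class(out) <- c("binned_rates", "data.frame")
  out
}

#' Standardize bin rates within participant and condition
#'
#' The sequence effect (better detection in the second-performed condition)
#' shifts whole rate profiles up or down; it is removed by normalizing the
#' ten bin rates within each participant x condition before re-testing and
#' before sine fitting. `method = "z"` (default) subtracts the mean and
#' divides by the sample SD across bins, so each profile has mean 0 and
#' unit variance; `method = "center"` subtracts the mean only. `NA` bins
#' stay `NA` and are excluded from the moments. A constant profile (zero
#' variance) cannot be z-scored and raises an error advising exclusion.
#'
#' @param rates a `binned_rates` table from [detection_rates()].
#' @param method `"z"` or `"center"`.
#' @return The input with a `z` column appended (class `binned_rates`).
#' @export
#' @examples
#' r <- data.frame(participant_id = "p1", condition = "sham", bin = 0:2,
#'                 rate = c(0.2, 0.4, 0.6), count = 10)
#' standardize_rates(r)$z # -1 0 1
standardize_rates <- function(rates, method = c("z", "center")) {
  method <- match.arg(method)
  key <- paste(rates$participant_id, rates$condition, sep = "\r")
  z <- rates$rate
  for (k in unique(key)) {
    i <- key == k
    v <- rates$rate[i]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      abort_invalid(sprintf("fewer than 2 non-missing bins for %s",
                            gsub("\r", " / ", k)))
    s <- sd(v[ok])
    if (method == "z" && s == 0)
      abort_invalid(sprintf(
        "constant rate vector for %s: zero variance, exclude this participant/condition from standardized analyses",
        gsub("\r", " / ", k)))
    z[i] <- if (method == "z") (v - mean(v[ok])) / s else v - mean(v[ok])
  }
  rates$z <- z
  class(rates) <- c("binned_rates", "data.frame")
  rates
}

#' Time-course detection rates over consecutive-trial bins
#'
#' Tracks detection over the session: per participant and condition the
#' trials are split, in presentation order, into consecutive bins of
#' `bin_size` trials (12 bins of 32 for the default 3 x 128 design, so
#' block boundaries fall exactly after bins 4 and 8). The same exclusions
#' as [detection_rates()] apply — catch and no-response trials are removed
#' from numerator and denominator but still occupy their position in the
#' consecutive-trial count.
#'
#' @param trials trial `data.frame`, ordered by presentation within each
#'   participant x condition (block then trial).
#' @param bin_size trials per time bin; must divide the per-condition trial
#'   count.
#' @return A long `data.frame` with `participant_id`, `condition`,
#'   `time_bin` (1-based), `rate`, `count`.
#' @export
timecourse_rates <- function(trials, bin_size = 32) {
  key <- paste(trials$participant_id, trials$condition, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(trials)), key), function(i) {
    tr <- trials[i, ]
    tr <- tr[order(tr$block, tr$trial), ]
    n <- nrow(tr)
    if (n %% bin_size != 0)
      abort_invalid(sprintf(
        "trial count %d for %s / %s is not divisible by bin_size = %d",
        n, tr$participant_id[1], tr$condition[1], bin_size))
    tb <- rep(seq_len(n / bin_size), each = bin_size)
    scored <- !tr$catch & tr$response %in% c("hit", "miss")
    hits <- tapply((tr$response == "hit") & scored, tb, sum)
    cnt <- tapply(scored, tb, sum)
    data.frame(participant_id = tr$participant_id[1],
               condition = tr$condition[1],
               time_bin = as.integer(names(cnt)),
               rate = ifelse(cnt > 0, as.numeric(hits) / as.numeric(cnt), NA_real_),
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$participant_id, out$condition, out$time_bin), ]
  rownames(out) <- NULL
  out
}
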