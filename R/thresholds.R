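#' Read an ethnographic forager table
#'
#' Expected CSV columns: `group_id` (unique), `mobility`
#' (`"fully_mobile"` or `"other"`), `bio12` (mean annual precipitation at
#' the group's location, mm/yr, positive).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_ethnographic_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ethnographic_table(tab)
}

validate_ethnographic_table <- function(tab) {
  need <- c("group_id", "mobility", "bio12")
  if (!all(need %in% names(tab)))
    stop("ethnographic table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$group_id)) stop("group_id values must be unique")
  if (any(!is.finite(tab$bio12)) || any(tab$bio12 <= 0))
    stop("bio12 must be positive and finite for every group")
  tab
}

#' Restrict an ethnographic table to fully mobile groups
#'
#' Partially sedentary groups are excluded before deriving habitability
#' envelopes, since the envelopes are meant to bound the precipitation niche
#' of mobile foragers. Row order is preserved.
#'
#' @param table Ethnographic data frame (see [read_ethnographic_table()]).
#' @return The subset with `mobility == "fully_mobile"`.
#' @export
filter_mobile_groups <- function(table) {
  table <- validate_ethnographic_table(table)
  out <- table[table$mobility == "fully_mobile", , drop = FALSE]
  if (nrow(out) == 0) stop("no fully mobile groups in table")
  rownames(out) <- NULL
  out
}

#' A lower/upper habitability envelope
#'
#' @param lower,upper Bounds in mm/yr, `0 <= lower <= upper`.
#' @param coverage Fraction of the distribution the envelope spans.
#' @param method How the envelope was derived (`"percentile"`,
#'   `"lognormal"`, or `"fixed"` for externally supplied bounds).
#' @return Object of class `threshold_pair`.
#' @export
threshold_pair <- function(lower, upper, coverage = NA_real_,
                           method = "fixed") {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1, length(upper) == 1)
  if (lower < 0 || lower > upper)
    stop("need 0 <= lower <= upper")
  structure(list(lower = lower, upper = upper, coverage = coverage,
                 method = method, zero_width = isTRUE(lower == upper)),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> [%g, %g] mm/yr (coverage %s, %s)%s\n",
              x$lower, x$upper,
              ifelse(is.na(x$coverage), "?", format(x$coverage)), x$method,
              if (x$zero_width) " [zero width]" else ""))
  invisible(x)
}

#' Derive a habitability envelope from precipitation values
#'
#' Two constructions are available. `"percentile"` (default) takes
#' symmetric-tail empirical quantiles at `(1 - coverage)/2` and
#' `1 - (1 - coverage)/2`, with linear interpolation between order
#' statistics (`stats::quantile` type 7), so results are reproducible
#' bit-for-bit. `"lognormal"` fits a normal to `log(values)` and returns
#' `exp(mu +/- z * sigma)` with `z` the two-sided normal quantile for the
#' requested coverage.
#'
#' A degenerate zero-width envelope (all values identical) is returned with
#' a warning and flagged via `$zero_width`.
#'
#' @param values Numeric vector of precipitation values (mm/yr), length >= 3.
#' @param coverage Fraction in (0, 1); 0.68 gives the narrow and 0.95 the
#'   broad envelope.
#' @param method `"percentile"` or `"lognormal"`.
#' @return A [threshold_pair()].
#' @export
derive_envelope <- function(values, coverage,
                            method = c("percentile", "lognormal")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage <= 0 || coverage >= 1)
    stop("coverage must be a single value in (0, 1)")
  tail <- (1 - coverage) / 2
  if (method == "percentile") {
    q <- unname(stats::quantile(values, probs = c(tail, 1 - tail),
                                type = 7, names = FALSE))
  } else {
    if (any(values <= 0))
      stop("lognormal method requires strictly positive values")
    lv <- log(values)
    z <- stats::qnorm(1 - tail)
    q <- exp(mean(lv) + c(-1, 1) * z * stats::sd(lv))
  }
  if (q[1] == q[2]) warning("degenerate zero-width envelope")
  threshold_pair(q[1], q[2], coverage = coverage, method = method)
}
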