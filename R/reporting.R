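#' Bland-Altman agreement
#'
#' Differences A - B with mean, SD (n-1 denominator) and 95% limits of
#' agreement (mean +/- 1.96 SD); per-pair (mean, difference) points are
#' returned for plotting.
#'
#' @param a,b paired measurements, mm (equal length, n >= 2); alternatively
#'   `a` may be a 2-column matrix/data.frame.
#' @return list(mean_diff, sd_diff, loa = c(lower, upper), n, points).
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) { b <- a[, 2]; a <- a[, 1] }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("bland_altman: need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(m - 1.96 * s, m + 1.96 * s),
       n = length(d),
       points = data.frame(mean = (a + b) / 2, difference = d))
}

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1): two-way model, absolute agreement, single measure, from the
#' standard mean-squares decomposition (subjects x raters):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param a,b paired measurements from the two raters (n >= 3);
#'   alternatively `a` may be a 2-column matrix/data.frame.
#' @return ICC value in (-1, 1].
#' @export
icc_two_way <- function(a, b = NULL) {
  if (is.null(b)) { b <- a[, 2]; a <- a[, 1] }
  ok <- is.finite(a) & is.finite(b)
  x <- cbind(a[ok], b[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop("icc_two_way: need at least 3 subjects")
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm - grand)^2)
  SSC <- n * sum((cm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(den) < 1e-12)
    stop("icc_two_way: zero total variance (degenerate input)")
  (MSR - MSE) / den
}

#' Agreement between two report batches
#'
#' Bland-Altman and ICC(A,1) per landmark across paired diameter reports
#' (observer vs observer, or pipeline vs manual measurements).  Both batches
#' must have the same length and landmark vocabulary.
#'
#' @param batch_a,batch_b lists of [measure_pair()] data.frames (one per
#'   case), or single data.frames.
#' @param column which diameter column to compare (default
#'   "baseline_mm").
#' @return data.frame(name, n, mean_diff_mm, sd_diff_mm, loa_lo, loa_hi,
#'   icc).
#' @export
evaluate_agreement <- function(batch_a, batch_b, column = "baseline_mm") {
  if (is.data.frame(batch_a)) batch_a <- list(batch_a)
  if (is.data.frame(batch_b)) batch_b <- list(batch_b)
  if (length(batch_a) != length(batch_b))
    stop("evaluate_agreement: batches have different lengths (",
         length(batch_a), " vs ", length(batch_b), ")")
  nms <- sort(batch_a[[1]]$name)
  for (r in c(batch_a, batch_b))
    if (!identical(sort(r$name), nms))
      stop("evaluate_agreement: mismatched landmark sets between reports")
  rows <- lapply(batch_a[[1]]$name, function(nm) {
    va <- vapply(batch_a, function(r) r[[column]][r$name == nm], numeric(1))
    vb <- vapply(batch_b, function(r) r[[column]][r$name == nm], numeric(1))
    ba <- bland_altman(va, vb)
    icc <- if (ba$n >= 3)
      tryCatch(icc_two_way(va, vb), error = function(e) NA_real_)
    else NA_real_
    data.frame(name = nm, n = ba$n, mean_diff_mm = ba$mean_diff,
               sd_diff_mm = ba$sd_diff, loa_lo = ba$loa[1],
               loa_hi = ba$loa[2], icc = icc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Import manual measurements from CSV
#'
#' Reads a long-format table with columns `case`, `landmark`, `diameter_mm`
#' (one row per case x landmark) and returns a batch of per-case report
#' data.frames suitable for [evaluate_agreement()].
#'
#' @param path CSV file.
#' @param column name to give the diameter column (default "baseline_mm").
#' @return named list of data.frame(name, <column>) per case.
#' @export
import_manual_measurements <- function(path, column = "baseline_mm") {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case", "landmark", "diameter_mm")
  if (!all(need %in% names(tab)))
    stop("import_manual_measurements: CSV must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$case), function(d) {
    out <- data.frame(name = d$landmark, stringsAsFactors = FALSE)
    out[[column]] <- d$diameter_mm
    out
  })
}
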