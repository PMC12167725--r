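# Pairwise reader/model agreement: Dice-Sorensen overlap, volume and LRF%
# differences, Spearman correlation, Bland-Altman limits of agreement, and
# a median (min-max) report in the conventional multi-reader layout.

#' Dice-Sorensen coefficient
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks agree perfectly (1.0), which
#' matters for solitary-kidney cases where both sources correctly segment
#' nothing on one side; exactly one empty mask gives 0.
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @return Overlap in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks must share geometry")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1.0)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d = x - y`: bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` with the n-1 denominator.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Object of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 2) stopf("Bland-Altman needs at least 2 paired measurements")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd = s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, limits of agreement [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (average ranks on ties).
#' Zero rank variance in either input leaves the correlation undefined and
#' raises an error.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 3) stopf("Spearman correlation needs n >= 3")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0)
    stopf("undefined correlation: zero rank variance")
  cor(x, y, method = "spearman")
}

#' Compare two segmentations of one case
#'
#' Per-kidney Dice and volume differences, and the LRF% difference, with
#' every difference oriented as (first source - second source).
#'
#' @param seg_a,seg_b [label_volume]s on the PET geometry.
#' @param pet The PET [image_volume] both segmentations are measured on.
#' @param case_id,source_a,source_b Identifiers carried into the record.
#' @return One-row data frame: `case_id`, `source_a`, `source_b`,
#'   `dsc_left`, `dsc_right`, `diff_vol_left_ml`, `diff_vol_right_ml`,
#'   `diff_lrf_ppt`.
#' @export
compare_pair <- function(seg_a, seg_b, pet, case_id = "case",
                         source_a = "a", source_b = "b") {
  assert_same_geometry(seg_a, seg_b, "segmentations")
  assert_same_geometry(seg_a, pet, "segmentation and pet")
  lrf_a <- compute_srf(pet, seg_a)$lrf_percent
  lrf_b <- compute_srf(pet, seg_b)$lrf_percent
  data.frame(
    case_id = case_id, source_a = source_a, source_b = source_b,
    dsc_left = dice(seg_a$data == 1L, seg_b$data == 1L),
    dsc_right = dice(seg_a$data == 2L, seg_b$data == 2L),
    diff_vol_left_ml = mask_volume_ml(seg_a, 1L) - mask_volume_ml(seg_b, 1L),
    diff_vol_right_ml = mask_volume_ml(seg_a, 2L) - mask_volume_ml(seg_b, 2L),
    diff_lrf_ppt = lrf_a - lrf_b,
    stringsAsFactors = FALSE)
}

#' Compare all segmentation sources over a set of cases
#'
#' Every ordered pair of sources is compared on every case (`k (k - 1)`
#' records per case for `k` sources), and per-source measurements (LRF%,
#' per-kidney volumes) are tabulated for the correlation analyses.
#'
#' @param cases List of cases; each a list with `case_id`, `pet` (an
#'   [image_volume]) and `sources` (a named list of [label_volume]s).
#' @return Object of class `srf_agreement`: list with `records` (all
#'   ordered pairwise [compare_pair] rows) and `measurements` (one row per
#'   case x source).
#' @export
evaluate_sources <- function(cases) {
  if (length(cases) == 0) stopf("`cases` must be non-empty")
  records <- list()
  meas <- list()
  for (case in cases) {
    srcs <- names(case$sources)
    for (s in srcs) {
      res <- compute_srf(case$pet, case$sources[[s]])
      meas[[length(meas) + 1L]] <- data.frame(
        case_id = case$case_id, source = s, lrf_percent = res$lrf_percent,
        vol_left_ml = res$left_volume_ml, vol_right_ml = res$right_volume_ml,
        stringsAsFactors = FALSE)
    }
    for (a in srcs) for (b in srcs) {
      if (a == b) next
      records[[length(records) + 1L]] <-
        compare_pair(case$sources[[a]], case$sources[[b]], case$pet,
                     case$case_id, a, b)
    }
  }
  structure(list(records = do.call(rbind, records),
                 measurements = do.call(rbind, meas)),
            class = "srf_agreement")
}

#' Summarize pairwise agreement in the standard multi-reader layout
#'
#' For each unordered source pair (reported in first-listed orientation):
#' median (min-max) of the volume difference and Dice pooled over both
#' kidneys, and of the LRF% difference per case; plus Spearman correlation
#' matrices for LRF% and renal volumes across sources, and a Bland-Altman
#' analysis of the LRF% measurements per pair.
#'
#' @param x An `srf_agreement` from [evaluate_sources], or a records data
#'   frame as produced by [compare_pair] (then correlation matrices are
#'   omitted).
#' @return Object of class `srf_agreement_summary` with elements `pairs`
#'   (data frame), `bland_altman` (named list), `spearman_lrf`,
#'   `spearman_volume` (matrices or `NULL`).
#' @export
summarize_agreement <- function(x) {
  if (inherits(x, "srf_agreement")) {
    records <- x$records
    meas <- x$measurements
  } else {
    records <- x
    meas <- NULL
  }
  if (is.null(records) || nrow(records) == 0) stopf("no comparison records")
  sources <- unique(c(records$source_a, records$source_b))
  pairs <- list(); ba <- list()
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    a <- records$source_a[i]; b <- records$source_b[i]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    sub <- records[records$source_a == a & records$source_b == b, ]
    dsc <- c(sub$dsc_left, sub$dsc_right)
    dv <- c(sub$diff_vol_left_ml, sub$diff_vol_right_ml)
    dl <- sub$diff_lrf_ppt
    pairs[[key]] <- data.frame(
      pair = paste(a, "vs", b),
      diff_vol_median = median(dv), diff_vol_min = min(dv),
      diff_vol_max = max(dv),
      dsc_median = median(dsc), dsc_min = min(dsc), dsc_max = max(dsc),
      diff_lrf_median = median(dl), diff_lrf_min = min(dl),
      diff_lrf_max = max(dl),
      n_cases = nrow(sub), stringsAsFactors = FALSE)
    if (!is.null(meas)) {
      la <- meas$lrf_percent[meas$source == a]
      lb <- meas$lrf_percent[meas$source == b]
      if (length(la) >= 2) ba[[paste(a, "vs", b)]] <- bland_altman(la, lb)
    } else if (nrow(sub) >= 2) {
      d <- sub$diff_lrf_ppt
      ba[[paste(a, "vs", b)]] <- bland_altman(d, numeric(length(d)))
    }
  }
  sp_lrf <- sp_vol <- NULL
  if (!is.null(meas) && length(sources) >= 2 &&
      length(unique(meas$case_id)) >= 3) {
    sp_lrf <- cross_spearman(meas, "lrf_percent", sources)
    sp_vol <- cross_spearman_volumes(meas, sources)
  }
  structure(list(pairs = do.call(rbind, pairs), bland_altman = ba,
                 spearman_lrf = sp_lrf, spearman_volume = sp_vol),
            class = "srf_agreement_summary")
}

cross_spearman <- function(meas, field, sources) {
  k <- length(sources)
  m <- matrix(NA_real_, k, k, dimnames = list(sources, sources))
  for (a in sources) for (b in sources) {
    xa <- meas[meas$source == a, ]
    xb <- meas[meas$source == b, ]
    xb <- xb[match(xa$case_id, xb$case_id), ]
    m[a, b] <- tryCatch(spearman(xa[[field]], xb[[field]]),
                        error = function(e) NA_real_)
  }
  m
}

cross_spearman_volumes <- function(meas, sources) {
  k <- length(sources)
  m <- matrix(NA_real_, k, k, dimnames = list(sources, sources))
  for (a in sources) for (b in sources) {
    xa <- meas[meas$source == a, ]
    xb <- meas[meas$source == b, ]
    xb <- xb[match(xa$case_id, xb$case_id), ]
    va <- c(xa$vol_left_ml, xa$vol_right_ml)
    vb <- c(xb$vol_left_ml, xb$vol_right_ml)
    keep <- va > 0 | vb > 0    # absent kidneys carry no volume information
    m[a, b] <- tryCatch(spearman(va[keep], vb[keep]),
                        error = function(e) NA_real_)
  }
  m
}

#' @export
print.srf_agreement_summary <- function(x, ...) {
  cat("Pairwise agreement, median (min-max):\n")
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("  %s\n", p$pair))
    cat(sprintf("    Diff_vol: %.1f (%.1f to %.1f) ml\n",
                p$diff_vol_median, p$diff_vol_min, p$diff_vol_max))
    cat(sprintf("    DSC: %.2f (%.2f to %.2f)\n",
                p$dsc_median, p$dsc_min, p$dsc_max))
    cat(sprintf("    Diff_LRF%%: %.1f (%.1f to %.1f) ppt\n",
                p$diff_lrf_median, p$diff_lrf_min, p$diff_lrf_max))
  }
  if (!is.null(x$spearman_lrf)) {
    cat("Spearman correlation, LRF%:\n")
    print(round(x$spearman_lrf, 3))
  }
  invisible(x)
}

#' Write an agreement report to disk
#'
#' Emits `report.csv` (the per-pair summary table) and `report.json` (the
#' full summary including Bland-Altman and correlation matrices).
#'
#' @param summary An `srf_agreement_summary`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(summary, dir) {
  stopifnot(inherits(summary, "srf_agreement_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(summary$pairs, file.path(dir, "report.csv"), row.names = FALSE)
  payload <- list(
    pairs = summary$pairs,
    bland_altman = lapply(summary$bland_altman, unclass),
    spearman_lrf = summary$spearman_lrf,
    spearman_volume = summary$spearman_volume)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot agreement: measurement ladder and Bland-Altman panels
#'
#' The ladder orders cases by their mean LRF% and shows each source's
#' measurement; one Bland-Altman panel is drawn per source pair.
#'
#' @param x An `srf_agreement` (from [evaluate_sources]).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.srf_agreement <- function(x, ...) {
  meas <- x$measurements
  sources <- unique(meas$source)
  case_means <- tapply(meas$lrf_percent, meas$case_id, mean)
  ord <- names(sort(case_means))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(1, length(ord)),
                 ylim = range(meas$lrf_percent),
                 xlab = "case (ordered by mean LRF%)", ylab = "LRF%",
                 main = "LRF% measurements")
  for (s in seq_along(sources)) {
    sub <- meas[meas$source == sources[s], ]
    graphics::points(match(sub$case_id, ord), sub$lrf_percent,
                     pch = s, col = s)
  }
  graphics::legend("topleft", legend = sources, pch = seq_along(sources),
                   col = seq_along(sources), bty = "n", cex = 0.8)
  if (length(sources) >= 2) {
    a <- sources[1]; b <- sources[2]
    la <- meas$lrf_percent[meas$source == a]
    lb <- meas$lrf_percent[meas$source == b]
    ba <- bland_altman(la, lb)
    graphics::plot((la + lb) / 2, la - lb, xlab = "mean LRF%",
                   ylab = sprintf("%s - %s (ppt)", a, b),
                   main = "Bland-Altman")
    graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high), lty = 2)
  }
  invisible(x)
}
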