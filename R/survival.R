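## Seed bank survival: the product statistic pl * ps, stratum aggregation,
## between-year decline, and a packet bootstrap for interval estimates.

#' Seed bank survival from retention and staining proportions
#'
#' Seed bank survival is the product of `pl`, the proportion of recovered
#' seeds that were retained (intact) at collection, and `ps`, the seed
#' staining rate (the proportion of assayed retained seeds showing any
#' stain, used as the viability estimate). Pure and deterministic;
#' vectorized over both arguments.
#'
#' @param pl Retained proportion(s) in \[0, 1\].
#' @param ps Staining rate(s) in \[0, 1\].
#' @return `pl * ps`.
#' @examples
#' survivalEstimate(0.16, 0.623)
#' @export
survivalEstimate <- function(pl, ps) {
  if (any(!is.finite(pl)) || any(pl < 0) || any(pl > 1))
    stop("pl must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
    stop("ps must lie in [0, 1]", call. = FALSE)
  pl * ps
}

#' Survival estimates from pooled packet counts
#'
#' Computes, per group, `pl` = retained / recovered seeds (unrecovered
#' seeds are excluded from the denominator), `ps` = stained / assayed
#' seeds, and `survival = pl * ps`, all from counts pooled over the group's
#' packets. A group with no retained seed has `survival = 0` regardless of
#' its (undefined) staining rate; a group with retained seed but no assayed
#' seed has `ps` and `survival` `NA`.
#'
#' Survival is normally computed per elementary stratum (species x cohort x
#' microhabitat x burial duration) and then averaged unweighted across
#' strata with [aggregateSurvival()]; pooling counts to a coarser grouping
#' first gives the alternative product-of-pooled-proportions path, which in
#' general differs (the product of averages is not the average of
#' products).
#'
#' @param x A [SeedPacketExperiment-class].
#' @param by Grouping label columns; default the elementary stratum.
#' @return data.frame with grouping labels, `n_recovered`, `n_retained`,
#'   `n_assayed`, `n_stained`, `pl`, `ps`, `survival`.
#' @examples
#' x <- simulateExperiment(calibratedScenario(rng_seed = 11))
#' est <- estimateSurvival(x)
#' aggregateSurvival(est, over = c("cohort", "microhabitat"))
#' @export
estimateSurvival <- function(x, by = c("species", "cohort", "microhabitat",
                                       "burial_seasons")) {
  ps_ <- summarizePools(x, by = by)
  out <- ps_[, intersect(names(ps_), c(by, "group")), drop = FALSE]
  out$n_recovered <- ps_$n_expended + ps_$n_retained
  out$n_retained <- ps_$n_retained
  out$n_assayed <- ps_$n_assayed
  out$n_stained <- ps_$n_stained
  out$pl <- ifelse(out$n_recovered > 0,
                   out$n_retained / out$n_recovered, NA_real_)
  out$ps <- ifelse(out$n_assayed > 0, out$n_stained / out$n_assayed,
                   NA_real_)
  out$survival <- ifelse(!is.na(out$pl) & out$pl == 0, 0, out$pl * out$ps)
  attr(out, "by") <- by
  out
}

#' Average survival estimates across strata
#'
#' Unweighted mean of group-level `pl`, `ps` and `survival` values across
#' the averaged-out labels. This is the convention behind statements such
#' as "survival averaged across species": each elementary stratum
#' contributes equally regardless of its packet or seed count. The result
#' records how many component groups entered each mean. Order of the input
#' rows is immaterial.
#'
#' @param estimates Output of [estimateSurvival()] (or any data.frame with
#'   `pl`, `ps`, `survival` and label columns).
#' @param over Label columns to average out.
#' @return data.frame keyed by the remaining label columns with columns
#'   `pl`, `ps`, `survival` (means of stratum values), `n_groups`, and
#'   `components` (the averaged-out group labels). Note `survival` is the
#'   mean of stratum-level products, not the product of the `pl` and `ps`
#'   means.
#' @export
aggregateSurvival <- function(estimates, over) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L,
            all(c("pl", "ps", "survival") %in% names(estimates)),
            all(over %in% names(estimates)))
  by <- attr(estimates, "by")
  if (is.null(by))
    by <- setdiff(names(estimates),
                  c("pl", "ps", "survival", "n_recovered", "n_retained",
                    "n_assayed", "n_stained", "n_groups", "components"))
  keep <- setdiff(by, over)
  key <- .groupKey(estimates, keep)
  mean_ <- function(col) as.numeric(tapply(estimates[[col]], key,
                                           mean, na.rm = TRUE))
  out <- if (length(keep)) {
    lab <- estimates[!duplicated(key), keep, drop = FALSE]
    lab <- lab[order(unique(key)), , drop = FALSE]
    rownames(lab) <- NULL
    lab
  } else data.frame(group = "all", stringsAsFactors = FALSE)
  out$pl <- mean_("pl")
  out$ps <- mean_("ps")
  out$survival <- mean_("survival")
  out$n_groups <- as.integer(tapply(!is.na(estimates$survival), key, sum))
  comp <- do.call(paste, c(estimates[intersect(over, names(estimates))],
                           sep = ":"))
  out$components <- as.character(tapply(comp, key,
                                        function(v) paste(sort(v),
                                                          collapse = "; ")))
  attr(out, "by") <- keep
  out
}

#' Between-year survival decline
#'
#' Percent decline in seed bank survival from the first to the second
#' growing season: `(s_year1 - s_year2) / s_year1 * 100`. Vectorized.
#'
#' @param s_year1,s_year2 Survival values on a common scale (proportions or
#'   percent). `s_year1` must be strictly positive.
#' @return Percent decline (negative if survival increased).
#' @examples
#' survivalDecline(18.9, 3.3)
#' @export
survivalDecline <- function(s_year1, s_year2) {
  if (any(!is.finite(s_year1)) || any(s_year1 <= 0))
    stop("s_year1 must be strictly positive: decline is undefined at 0",
         call. = FALSE)
  (s_year1 - s_year2) / s_year1 * 100
}

#' Round half away from zero
#'
#' Report-time rounding matching how printed percentages are rounded
#' (half-up), unlike [round()]'s round-half-to-even. All internal
#' computation is carried at full floating precision; use this only when
#' formatting results.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' roundHalfUp(4.95, 1)  # 5.0, where round() gives 4.9 or 5.0 by parity
#' @export
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Packet bootstrap intervals for survival
#'
#' Nonparametric bootstrap over packets: within each group, packets are
#' resampled with replacement, counts re-pooled, and `pl`, `ps` and
#' `survival` recomputed. Survival is a product of two binomial proportions
#' with no standard interval; this bootstrap is a package extension and the
#' output is labelled as such.
#'
#' @param x A [SeedPacketExperiment-class].
#' @param by Grouping columns (default the elementary stratum).
#' @param n_boot Number of resamples (default 2000).
#' @param level Interval coverage (default 0.95).
#' @param seed RNG seed.
#' @return [estimateSurvival()] output with `survival_lo`, `survival_hi`
#'   percentile bounds and attribute `interval = "packet bootstrap (package extension)"`.
#' @export
bootstrapSurvival <- function(x, by = c("species", "cohort", "microhabitat",
                                        "burial_seasons"),
                              n_boot = 2000L, level = 0.95, seed = 1L) {
  stopifnot(is(x, "SeedPacketExperiment"), n_boot >= 2L)
  est <- estimateSurvival(x, by = by)
  df <- x@packets
  key <- .groupKey(df, by)
  set.seed(seed)
  alpha <- (1 - level) / 2
  lo <- hi <- numeric(nrow(est))
  groups <- levels(key)
  for (gi in seq_along(groups)) {
    idx <- which(key == groups[gi])
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- sample(idx, length(idx), replace = TRUE)
      ret <- sum(df$n_retained[take])
      rec <- sum(df$n_expended[take]) + ret
      asy <- sum(df$n_assayed[take])
      stn <- sum(df$n_stained[take])
      pl <- if (rec > 0) ret / rec else NA_real_
      if (!is.na(pl) && pl == 0) return(0)
      ps <- if (asy > 0) stn / asy else NA_real_
      pl * ps
    }, numeric(1))
    qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo[gi] <- qs[1]; hi[gi] <- qs[2]
  }
  est$survival_lo <- lo
  est$survival_hi <- hi
  attr(est, "interval") <- "packet bootstrap (package extension)"
  attr(est, "n_boot") <- n_boot
  est
}
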