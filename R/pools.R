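## Pool accounting: partition seed counts into the conceptual-model pools
## (expended F = decayed A + germinated B; retained C; retained live D /
## dead E from the staining assay) and emit conservative Sankey flow tables.

.groupKey <- function(df, by) {
  if (!length(by)) return(factor(rep("all", nrow(df))))
  stopifnot(all(by %in% names(df)))
  interaction(df[by], drop = TRUE, sep = ":")
}

#' Summarize seed pools by group
#'
#' Sums packet counts within groups and expresses each pool as a proportion
#' of that group's seed bank (all seeds sown into the group's packets,
#' the 100% baseline). The expended pool F combines germinated and decayed
#' seeds, which are indistinguishable at collection; the retained pool C is
#' intact seed; D (stained = live) and E (unstained = dead) partition the
#' assayed subset of C. The staining rate is the assay-scope proportion
#' `D / (D + E)`. Seeds never recovered are reported as `n_unrecovered` and
#' carry their own share of the seed bank.
#'
#' @param x A [SeedPacketExperiment-class].
#' @param by Character vector of grouping label columns (any subset of
#'   species / cohort / microhabitat / burial_seasons / collection_year /
#'   site / plot); empty for a single overall group.
#' @param drop_empty Groups without packets (absent label combinations) are
#'   omitted with a warning rather than producing zero divisions.
#' @return data.frame with one row per group: the grouping labels,
#'   `n_total`, `n_expended`, `n_retained`, `n_unrecovered`, `n_assayed`,
#'   `n_stained`, `n_unstained`, the seed-bank-scope proportions
#'   `prop_expended`, `prop_retained`, `prop_unrecovered`, and the
#'   assay-scope `staining_rate` (`NA` when nothing was assayed).
#' @examples
#' x <- simulateExperiment(calibratedScenario(rng_seed = 3))
#' summarizePools(x, by = c("species", "burial_seasons"))
#' @export
summarizePools <- function(x, by = character(), drop_empty = TRUE) {
  stopifnot(is(x, "SeedPacketExperiment"))
  df <- x@packets
  if (!nrow(df)) stop("empty packet collection", call. = FALSE)
  key <- .groupKey(df, by)
  if (drop_empty && nlevels(key) > length(unique(key)))
    warning("empty groups omitted: ",
            paste(setdiff(levels(key), unique(key)), collapse = ", "))
  key <- droplevels(key)
  sums <- function(col) as.integer(tapply(df[[col]], key, sum))
  out <- if (length(by)) {
    lab <- df[!duplicated(key), by, drop = FALSE]
    lab <- lab[order(unique(key)), , drop = FALSE]
    rownames(lab) <- NULL
    lab
  } else data.frame(group = "all", stringsAsFactors = FALSE)
  out$n_total <- sums("seeds_sown")
  out$n_expended <- sums("n_expended")
  out$n_retained <- sums("n_retained")
  out$n_unrecovered <- out$n_total - out$n_expended - out$n_retained
  out$n_assayed <- sums("n_assayed")
  out$n_stained <- sums("n_stained")
  out$n_unstained <- out$n_assayed - out$n_stained
  out$prop_expended <- out$n_expended / out$n_total
  out$prop_retained <- out$n_retained / out$n_total
  out$prop_unrecovered <- out$n_unrecovered / out$n_total
  out$staining_rate <- ifelse(out$n_assayed > 0,
                              out$n_stained / out$n_assayed, NA_real_)
  attr(out, "by") <- by
  out
}

#' Live and dead seed pools with resolvable and unresolvable parts
#'
#' The live pool G = germinated (B) + retained live (D) and the dead pool
#' H = decayed (A) + retained dead (E) are not point-identified, because A
#' and B cannot be separated within the expended pool F at collection. They
#' are therefore reported as intervals: G ranges over `[D, D + F]` and H
#' over `[E, E + F]` (as proportions of the seed bank). For display, F is
#' split equally between A and B; this equal split is a visualization
#' convention only, never an estimate, and is tagged as such in the output.
#'
#' D and E here are pool-scale values: the staining rate `D/(D+E)` observed
#' on the assayed subset is applied to all of the retained pool C.
#'
#' @param summary A pool summary from [summarizePools()].
#' @return The summary with added proportion columns `pool_live_D`,
#'   `pool_dead_E`, `live_G_min`, `live_G_max`, `dead_H_min`, `dead_H_max`,
#'   `display_decayed_A`, `display_germinated_B`, and an attribute
#'   `display_rule = "expended pool split equally between A and B (display convention)"`.
#' @examples
#' x <- simulateExperiment(calibratedScenario(rng_seed = 3))
#' liveDeadPools(summarizePools(x, "species"))[, c("live_G_min", "live_G_max")]
#' @export
liveDeadPools <- function(summary) {
  stopifnot(is.data.frame(summary),
            all(c("n_total", "prop_expended", "prop_retained",
                  "staining_rate") %in% names(summary)))
  sr <- summary$staining_rate
  D <- summary$prop_retained * sr
  E <- summary$prop_retained * (1 - sr)
  F_ <- summary$prop_expended
  summary$pool_live_D <- D
  summary$pool_dead_E <- E
  summary$live_G_min <- D
  summary$live_G_max <- D + F_
  summary$dead_H_min <- E
  summary$dead_H_max <- E + F_
  summary$display_decayed_A <- F_ / 2
  summary$display_germinated_B <- F_ / 2
  attr(summary, "display_rule") <-
    "expended pool split equally between A and B (display convention)"
  summary
}

#' Sankey flow table for seed bank pools
#'
#' Converts pool summaries into proportionally accurate Sankey flows over
#' the node set seed bank, decayed (A), germinated (B), retained (C), assay,
#' retained live (D) and retained dead (E). Magnitudes are proportions of
#' the group's seed bank; the unresolvable expended pool is displayed split
#' equally between A and B (a convention, see [liveDeadPools()]); the
#' assayed subsample is scaled so that C's children reflect the staining
#' rate `D/(D+E)` applied to all of C. Mass is conserved at every internal
#' node; root outflows sum to the recovered fraction of the seed bank.
#'
#' @param summary A pool summary from [summarizePools()] (one or more rows).
#' @return data.frame with columns `group`, `source`, `target`, `value`,
#'   `note`. Groups with retained seed but no assay keep C unsplit and are
#'   flagged in `note`.
#' @seealso [writeSankey()]
#' @export
sankeyFlows <- function(summary) {
  stopifnot(is.data.frame(summary), nrow(summary) >= 1L)
  by <- attr(summary, "by")
  grp <- if (!is.null(by) && length(by))
    do.call(paste, c(summary[by], sep = ":"))
  else if ("group" %in% names(summary)) as.character(summary$group)
  else as.character(seq_len(nrow(summary)))
  out <- vector("list", nrow(summary))
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    fE <- s$prop_expended
    fC <- s$prop_retained
    rows <- data.frame(
      group = grp[i],
      source = c("seed bank", "seed bank", "seed bank"),
      target = c("decayed (A)", "germinated (B)", "retained (C)"),
      value = c(fE / 2, fE / 2, fC),
      note = c("equal A/B split (display convention)",
               "equal A/B split (display convention)", ""),
      stringsAsFactors = FALSE
    )
    if (s$n_assayed > 0) {
      sr <- s$staining_rate
      rows <- rbind(rows, data.frame(
        group = grp[i],
        source = c("retained (C)", "assay", "assay"),
        target = c("assay", "retained live (D)", "retained dead (E)"),
        value = c(fC, fC * sr, fC * (1 - sr)),
        note = c("", "staining rate applied to all of C",
                 "staining rate applied to all of C"),
        stringsAsFactors = FALSE
      ))
    } else if (s$n_retained > 0) {
      rows$note[rows$target == "retained (C)"] <-
        "no assay: retained pool left unsplit"
    }
    out[[i]] <- rows
  }
  flows <- do.call(rbind, out)
  rownames(flows) <- NULL
  .checkSankeyConservation(flows)
  flows
}

.checkSankeyConservation <- function(flows, tol = 1e-9) {
  for (g in unique(flows$group)) {
    f <- flows[flows$group == g, ]
    internal <- intersect(unique(f$target), unique(f$source))
    for (node in internal) {
      inflow <- sum(f$value[f$target == node])
      outflow <- sum(f$value[f$source == node])
      if (abs(inflow - outflow) > tol)
        stop(sprintf("Sankey conservation violated at node '%s' (group %s): in %.12g out %.12g",
                     node, g, inflow, outflow), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write Sankey flows as JSON and CSV
#'
#' Emits the flow list in the `{source, target, value}` form consumed by
#' standard Sankey plotting tools, plus an equivalent CSV.
#'
#' @param flows Output of [sankeyFlows()].
#' @param json,csv Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
writeSankey <- function(flows, json = NULL, csv = NULL) {
  stopifnot(is.data.frame(flows),
            all(c("group", "source", "target", "value") %in% names(flows)))
  written <- character()
  if (!is.null(json)) {
    payload <- lapply(split(flows, flows$group), function(f) {
      lapply(seq_len(nrow(f)), function(i)
        list(source = f$source[i], target = f$target[i],
             value = f$value[i], note = f$note[i]))
    })
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json)
  }
  if (!is.null(csv)) {
    write.csv(flows, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  invisible(written)
}
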