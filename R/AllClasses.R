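## Central S4 containers: packet-level observations and simulation scenarios.

#' Packet table schema
#'
#' Column names, column types and the admissible microhabitat vocabulary for
#' packet-level seed-fate tables. The same schema is used for simulator
#' output and analyzer input; unknown microhabitat labels are errors, never
#' coerced.
#'
#' @return A list with elements `columns` (named character vector of column
#'   types), `count_columns`, `label_columns` and `microhabitats`.
#' @examples
#' packetSchema()$microhabitats
#' @export
packetSchema <- function() {
  list(
    columns = c(
      packet_id       = "character",
      species         = "character",
      cohort          = "character",
      site            = "character",
      plot            = "character",
      microhabitat    = "character",
      burial_seasons  = "integer",
      collection_year = "character",
      seeds_sown      = "integer",
      n_expended      = "integer",
      n_retained      = "integer",
      n_assayed       = "integer",
      n_stained       = "integer"
    ),
    count_columns = c("seeds_sown", "n_expended", "n_retained",
                      "n_assayed", "n_stained"),
    label_columns = c("species", "cohort", "site", "plot", "microhabitat",
                      "collection_year"),
    microhabitats = c("control", "runoff", "shade")
  )
}

.validPackets <- function(df) {
  sch <- packetSchema()
  missing <- setdiff(names(sch$columns), names(df))
  if (length(missing))
    return(sprintf("schema error: missing column(s) %s",
                   paste(missing, collapse = ", ")))
  bad <- function(id, rule) sprintf("packet '%s' violates: %s", id, rule)
  msgs <- character()
  for (cc in sch$count_columns) {
    v <- df[[cc]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      i <- which(!is.finite(v) | v < 0 | v != round(v))[1L]
      msgs <- c(msgs, bad(df$packet_id[i],
                          sprintf("%s must be a non-negative integer count", cc)))
    }
  }
  if (length(msgs)) return(msgs)
  chk <- function(cond, rule) {
    if (any(cond)) bad(df$packet_id[which(cond)[1L]], rule) else character()
  }
  msgs <- c(
    msgs,
    chk(df$n_expended + df$n_retained > df$seeds_sown,
        "n_expended + n_retained <= seeds_sown"),
    chk(df$n_assayed > df$n_retained, "n_assayed <= n_retained"),
    chk(df$n_stained > df$n_assayed, "n_stained <= n_assayed"),
    chk(!(df$microhabitat %in% sch$microhabitats),
        sprintf("microhabitat must be one of {%s}",
                paste(sch$microhabitats, collapse = ", "))),
    chk(!(df$burial_seasons %in% c(1L, 2L)), "burial_seasons must be 1 or 2")
  )
  if (anyDuplicated(df$packet_id))
    msgs <- c(msgs, sprintf("packet '%s' violates: packet_id must be unique",
                            df$packet_id[duplicated(df$packet_id)][1L]))
  if (length(msgs)) msgs else TRUE
}

#' SeedPacketExperiment: validated packet-level seed-fate observations
#'
#' One row per buried seed packet, holding its stratum labels (species, seed
#' cohort, site, plot, microhabitat, burial duration, collection year) and
#' per-class seed counts: seeds sown, expended seeds (germinated or decayed,
#' indistinguishable at collection), retained (intact) seeds, retained seeds
#' entered into the staining assay, and assayed seeds showing any stain.
#' Seeds unaccounted for (`seeds_sown - n_expended - n_retained`) are
#' tracked as unrecovered and excluded from all proportion denominators.
#'
#' Validity enforces, per packet: all counts non-negative integers;
#' `n_expended + n_retained <= seeds_sown`; `n_assayed <= n_retained`;
#' `n_stained <= n_assayed`; microhabitat in the [packetSchema()]
#' vocabulary; `burial_seasons` 1 or 2; unique `packet_id`. Violations are
#' reported with the offending packet id and rule.
#'
#' @slot packets data.frame in the [packetSchema()] layout, ordered by
#'   `packet_id`.
#' @seealso [SeedPacketExperiment()], [readPackets()], [summarizePools()]
#' @aliases SeedPacketExperiment-class
#' @exportClass SeedPacketExperiment
setClass("SeedPacketExperiment", slots = c(packets = "data.frame"))

setValidity("SeedPacketExperiment", function(object) {
  .validPackets(object@packets)
})

#' Construct a SeedPacketExperiment from a packet table
#'
#' @param packets data.frame with the [packetSchema()] columns, one row per
#'   packet. Count columns are coerced to integer; rows are ordered by
#'   `packet_id`.
#' @return A [SeedPacketExperiment-class] object.
#' @examples
#' df <- data.frame(packet_id = "p1", species = "E. mohavense",
#'   cohort = "2015", site = "caliche_pan", plot = "plot_01",
#'   microhabitat = "control", burial_seasons = 1L, collection_year = "2017",
#'   seeds_sown = 18L, n_expended = 6L, n_retained = 12L,
#'   n_assayed = 6L, n_stained = 3L)
#' SeedPacketExperiment(df)
#' @export
SeedPacketExperiment <- function(packets) {
  sch <- packetSchema()
  stopifnot(is.data.frame(packets))
  missing <- setdiff(names(sch$columns), names(packets))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  packets <- packets[, names(sch$columns), drop = FALSE]
  for (cc in names(sch$columns)) {
    packets[[cc]] <- switch(sch$columns[[cc]],
      character = as.character(packets[[cc]]),
      integer   = {
        v <- packets[[cc]]
        if (is.numeric(v) && all(is.finite(v)) && all(v == round(v)))
          as.integer(round(v)) else v
      })
  }
  packets <- packets[order(packets$packet_id), , drop = FALSE]
  rownames(packets) <- NULL
  msg <- .validPackets(packets)
  if (!isTRUE(msg)) stop("validation error: ", paste(msg, collapse = "; "),
                         call. = FALSE)
  new("SeedPacketExperiment", packets = packets)
}

setMethod("show", "SeedPacketExperiment", function(object) {
  df <- object@packets
  cat(sprintf("SeedPacketExperiment with %d packets, %d seeds sown\n",
              nrow(df), sum(df$seeds_sown)))
  if (nrow(df)) {
    cat(sprintf("  species:       %s\n",
                paste(sort(unique(df$species)), collapse = ", ")))
    cat(sprintf("  cohorts:       %s | collection years: %s\n",
                paste(sort(unique(df$cohort)), collapse = ", "),
                paste(sort(unique(df$collection_year)), collapse = ", ")))
    cat(sprintf("  microhabitats: %s\n",
                paste(sort(unique(df$microhabitat)), collapse = ", ")))
    cat(sprintf("  recovered %d | expended %d | retained %d | assayed %d | stained %d\n",
                sum(df$n_expended + df$n_retained), sum(df$n_expended),
                sum(df$n_retained), sum(df$n_assayed), sum(df$n_stained)))
  }
  invisible(NULL)
})

#' @describeIn SeedPacketExperiment Number of packets.
#' @param x,object A `SeedPacketExperiment`.
#' @export
setMethod("length", "SeedPacketExperiment", function(x) nrow(x@packets))

#' FateScenario: a multistate seed-fate simulation scenario
#'
#' Defines, per elementary stratum (species x cohort x microhabitat) and per
#' burial season, the transition probabilities of the seed fate model, plus
#' the packet allocation design and assay plan. An intact live seed may,
#' each season, become expended (germinate or decay, probability
#' `p_expend`), die in place while remaining intact (`p_die`), or stay
#' intact and alive. An intact dead seed may become expended with
#' probability `p_expend_dead` (equal to `p_expend` by default: seed-coat
#' decay is viability-blind). Retained seeds at collection are assayed in a
#' seeded random subsample of size `ceiling(assay_fraction * n_retained)`;
#' a live assayed seed stains with probability `stain_sensitivity`, a dead
#' one with `1 - stain_specificity`.
#'
#' @slot design data.frame with columns `species`, `cohort`, `n_packets`,
#'   `seeds_per_packet` (one row per species x cohort allocation).
#' @slot hazards data.frame with columns `species`, `cohort`,
#'   `microhabitat`, `season` (1 or 2), `p_expend`, `p_die`,
#'   `p_expend_dead`; one row per stratum x season.
#' @slot initial_viability Probability a sown seed is alive at burial.
#' @slot assay_fraction Proportion of retained seeds assayed, in (0, 1].
#' @slot stain_sensitivity,stain_specificity Assay error model.
#' @slot microhabitats,collection_years Labels; packets are split evenly
#'   across microhabitats and then evenly across collection years
#'   (collection year k implies burial_seasons = k).
#' @slot n_plots Plots per site over which packets are placed round-robin.
#' @slot rng_seed Root seed; per-stratum substreams are derived from it so
#'   adding a stratum does not perturb the others.
#' @seealso [FateScenario()], [simulateExperiment()], [impliedPools()],
#'   [scenarioFromPools()], [calibratedScenario()]
#' @aliases FateScenario-class
#' @exportClass FateScenario
setClass("FateScenario", slots = c(
  design            = "data.frame",
  hazards           = "data.frame",
  initial_viability = "numeric",
  assay_fraction    = "numeric",
  stain_sensitivity = "numeric",
  stain_specificity = "numeric",
  microhabitats     = "character",
  collection_years  = "character",
  n_plots           = "integer",
  rng_seed          = "integer"
))

setValidity("FateScenario", function(object) {
  msgs <- character()
  d <- object@design
  need_d <- c("species", "cohort", "n_packets", "seeds_per_packet")
  if (!all(need_d %in% names(d)))
    return(paste("design must have columns",
                 paste(need_d, collapse = ", ")))
  h <- object@hazards
  need_h <- c("species", "cohort", "microhabitat", "season",
              "p_expend", "p_die", "p_expend_dead")
  if (!all(need_h %in% names(h)))
    return(paste("hazards must have columns",
                 paste(need_h, collapse = ", ")))
  pr <- c(h$p_expend, h$p_die, h$p_expend_dead,
          object@initial_viability, object@stain_sensitivity,
          object@stain_specificity)
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  else if (any(h$p_expend + h$p_die > 1 + 1e-12))
    msgs <- c(msgs, "p_expend + p_die must be <= 1 for every stratum/season")
  if (!(object@assay_fraction > 0 && object@assay_fraction <= 1))
    msgs <- c(msgs, "assay_fraction must lie in (0, 1]")
  if (!all(h$season %in% c(1, 2)))
    msgs <- c(msgs, "season must be 1 or 2")
  ## every stratum needs both seasons so model-implied pools are closed-form
  key <- interaction(h$species, h$cohort, h$microhabitat, drop = TRUE)
  if (any(tapply(h$season, key, function(s) !setequal(s, 1:2))))
    msgs <- c(msgs, "every stratum must define hazards for seasons 1 and 2")
  if (length(object@collection_years) != 2L)
    msgs <- c(msgs, "exactly two collection years are required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FateScenario
#'
#' @param design data.frame of packet allocations: `species`, `cohort`,
#'   `n_packets`, `seeds_per_packet`. See [eriophyllumDesign()] for the
#'   default two-congener allocation.
#' @param hazards data.frame of per-stratum, per-season fate probabilities
#'   (`species`, `cohort`, `microhabitat`, `season`, `p_expend`, `p_die`,
#'   and optionally `p_expend_dead`, which defaults to `p_expend`).
#' @param initial_viability Probability a sown seed is alive at burial
#'   (default 1).
#' @param assay_fraction Proportion of retained seeds assayed (default 0.5).
#' @param stain_sensitivity,stain_specificity Staining assay error model
#'   (defaults 1: a perfect assay).
#' @param microhabitats Microhabitat labels (default from [packetSchema()]).
#' @param collection_years Two labels; the k-th implies k burial seasons.
#' @param n_plots Plots per site (default 20).
#' @param rng_seed Root seed (default 1).
#' @return A [FateScenario-class] object.
#' @export
FateScenario <- function(design, hazards,
                         initial_viability = 1,
                         assay_fraction = 0.5,
                         stain_sensitivity = 1,
                         stain_specificity = 1,
                         microhabitats = packetSchema()$microhabitats,
                         collection_years = c("2017", "2018"),
                         n_plots = 20L,
                         rng_seed = 1L) {
  design <- data.frame(as.data.frame(design)[
    c("species", "cohort", "n_packets", "seeds_per_packet")],
    stringsAsFactors = FALSE)
  design$n_packets <- as.integer(design$n_packets)
  design$seeds_per_packet <- as.integer(design$seeds_per_packet)
  hazards <- as.data.frame(hazards)
  if (is.null(hazards$p_expend_dead))
    hazards$p_expend_dead <- hazards$p_expend
  for (cc in c("species", "cohort")) {
    design[[cc]] <- as.character(design[[cc]])
    hazards[[cc]] <- as.character(hazards[[cc]])
  }
  hazards$microhabitat <- as.character(hazards$microhabitat)
  obj <- new("FateScenario",
             design = design, hazards = hazards,
             initial_viability = initial_viability,
             assay_fraction = assay_fraction,
             stain_sensitivity = stain_sensitivity,
             stain_specificity = stain_specificity,
             microhabitats = microhabitats,
             collection_years = as.character(collection_years),
             n_plots = as.integer(n_plots),
             rng_seed = as.integer(rng_seed))
  validObject(obj)
  obj
}

setMethod("show", "FateScenario", function(object) {
  cat(sprintf("FateScenario: %d design rows, %d strata, %d packets / %d seeds\n",
              nrow(object@design),
              nrow(unique(object@hazards[, c("species", "cohort",
                                             "microhabitat")])),
              sum(object@design$n_packets),
              sum(object@design$n_packets * object@design$seeds_per_packet)))
  cat(sprintf("  initial viability %.3g | assay fraction %.3g | stain sens/spec %.3g/%.3g\n",
              object@initial_viability, object@assay_fraction,
              object@stain_sensitivity, object@stain_specificity))
  cat(sprintf("  microhabitats: %s | collection years: %s | seed %d\n",
              paste(object@microhabitats, collapse = ", "),
              paste(object@collection_years, collapse = ", "),
              object@rng_seed))
  invisible(NULL)
})

#' Accessors for packet and scenario containers
#'
#' `packets()` returns the validated packet table of a
#' [SeedPacketExperiment-class]; `designOf()` returns the allocation design
#' of a [FateScenario-class] or the experiment-wide design implied by a
#' packet table; `hazardsOf()` returns a scenario's per-stratum seasonal
#' fate probabilities.
#'
#' @param x A `SeedPacketExperiment` or `FateScenario`.
#' @return A data.frame.
#' @name accessors
#' @examples
#' sc <- calibratedScenario()
#' head(hazardsOf(sc))
#' designOf(sc)
NULL

#' @rdname accessors
#' @export
setGeneric("packets", function(x) standardGeneric("packets"))

#' @rdname accessors
#' @export
setMethod("packets", "SeedPacketExperiment", function(x) x@packets)

#' @rdname accessors
#' @export
setGeneric("designOf", function(x) standardGeneric("designOf"))

#' @rdname accessors
#' @export
setMethod("designOf", "FateScenario", function(x) x@design)

#' @rdname accessors
#' @export
setMethod("designOf", "SeedPacketExperiment", function(x) {
  df <- x@packets
  agg <- aggregate(cbind(n_packets = rep(1L, nrow(df))) ~ species + cohort,
                   data = df, FUN = sum)
  spp <- aggregate(seeds_sown ~ species + cohort, data = df,
                   FUN = function(v) unique(v)[1L])
  agg$seeds_per_packet <- spp$seeds_sown[match(
    paste(agg$species, agg$cohort), paste(spp$species, spp$cohort))]
  agg[order(agg$species, agg$cohort), ]
})

#' @rdname accessors
#' @export
setGeneric("hazardsOf", function(x) standardGeneric("hazardsOf"))

#' @rdname accessors
#' @export
setMethod("hazardsOf", "FateScenario", function(x) x@hazards)
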