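## Tabular I/O and design arithmetic for packet-level seed-fate tables.

#' Read a packet table from CSV
#'
#' Reads a packet-level seed-fate table (RFC 4180 CSV, UTF-8, header
#' required, one row per packet) and validates every row against the packet
#' invariants. The same schema is written by [simulateExperiment()] via
#' [writePackets()], so simulator output and analyzer input round-trip.
#'
#' @param file Path to a CSV file with a header naming every
#'   [packetSchema()] column.
#' @return A [SeedPacketExperiment-class], rows ordered by `packet_id`.
#' @examples
#' x <- simulateExperiment(calibratedScenario(rng_seed = 7))
#' f <- tempfile(fileext = ".csv")
#' writePackets(x, f)
#' y <- readPackets(f)
#' identical(packets(x), packets(y))
#' @seealso [writePackets()], [SeedPacketExperiment()]
#' @export
readPackets <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = TRUE)
  sch <- packetSchema()
  missing <- setdiff(names(sch$columns), names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cc in names(sch$columns))
    if (sch$columns[[cc]] == "integer") {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      if (any(is.na(v)))
        stop("validation error: packet '",
             df$packet_id[which(is.na(v))[1L]],
             "' violates: ", cc, " must be a non-negative integer count",
             call. = FALSE)
      df[[cc]] <- v
    }
  SeedPacketExperiment(df)
}

#' Write a packet table to CSV
#'
#' @param x A [SeedPacketExperiment-class].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
writePackets <- function(x, file) {
  stopifnot(is(x, "SeedPacketExperiment"))
  write.csv(x@packets, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Merge packets collected at the same location
#'
#' Combines packets of the same seed cohort collected in the same location
#' (by default: same species, cohort, microhabitat, collection year and
#' plot) by summing their seed counts. This is the explicit, logged
#' pre-analysis step used before fitting packet-level proportion models;
#' it is never performed implicitly.
#'
#' @param x A [SeedPacketExperiment-class].
#' @param by Character vector of grouping label columns. `burial_seasons`
#'   must be constant within every group (it is whenever `collection_year`
#'   is part of `by`).
#' @param verbose Log the merge to `stderr` (default `TRUE`).
#' @return A [SeedPacketExperiment-class] with one row per group; merged
#'   `packet_id`s are the group labels joined by `"."`.
#' @export
mergePackets <- function(x, by = c("species", "cohort", "microhabitat",
                                   "collection_year", "plot"),
                         verbose = TRUE) {
  stopifnot(is(x, "SeedPacketExperiment"))
  df <- x@packets
  sch <- packetSchema()
  stopifnot(all(by %in% c(sch$label_columns, "burial_seasons")))
  key <- interaction(df[by], drop = TRUE, sep = ".")
  bs <- tapply(df$burial_seasons, key, function(v) length(unique(v)))
  if (any(bs > 1L))
    stop("cannot merge packets with differing burial_seasons; include ",
         "'collection_year' in `by`", call. = FALSE)
  first <- function(v) v[1L]
  out <- df[!duplicated(key), , drop = FALSE]
  out <- out[order(unique(key)), , drop = FALSE]
  for (cc in sch$count_columns)
    out[[cc]] <- as.integer(tapply(df[[cc]], key, sum))
  for (cc in setdiff(sch$label_columns, by))
    out[[cc]] <- as.character(tapply(df[[cc]], key,
                                     function(v) paste(sort(unique(v)),
                                                       collapse = "+")))
  out$packet_id <- levels(key)
  if (verbose)
    message(sprintf("mergePackets: %d packets -> %d merged rows by {%s}",
                    nrow(df), nrow(out), paste(by, collapse = ", ")))
  SeedPacketExperiment(out)
}

#' The two-congener packet allocation design
#'
#' The default experimental design: two desert annual congeners, a rare
#' species (*Eriophyllum mohavense*) and a common one (*E. wallacei*), each
#' contributing a 2015 and a 2016 seed cohort. Per species, 90 packets of
#' the 2015 cohort and 180 of the 2016 cohort are allocated; seeds per
#' packet follow seed availability (18 and 9 for the rare species, 14 and 2
#' for the common one), for 540 packets and 4860 seeds in total. Packets
#' are distributed evenly among control, runoff and shade microhabitats and
#' then evenly across the two collection years.
#'
#' @return data.frame with columns `species`, `cohort`, `n_packets`,
#'   `seeds_per_packet` and attributes `microhabitats`, `collection_years`,
#'   `split_rule` (`"even"`).
#' @examples
#' allocationTotals(eriophyllumDesign())
#' @export
eriophyllumDesign <- function() {
  d <- data.frame(
    species = rep(c("E. mohavense", "E. wallacei"), each = 2L),
    cohort = rep(c("2015", "2016"), 2L),
    n_packets = c(90L, 180L, 90L, 180L),
    seeds_per_packet = c(18L, 9L, 14L, 2L),
    stringsAsFactors = FALSE
  )
  attr(d, "microhabitats") <- packetSchema()$microhabitats
  attr(d, "collection_years") <- c("2017", "2018")
  attr(d, "split_rule") <- "even"
  d
}

#' Packet and seed totals of an allocation design
#'
#' Per-row and grand totals of packets and seeds for an allocation design.
#' Under the `"even"` split rule, every row's packet count must be divisible
#' by the number of microhabitats.
#'
#' @param design data.frame with columns `species`, `cohort`, `n_packets`,
#'   `seeds_per_packet`; e.g. [eriophyllumDesign()]. May have zero rows.
#' @param microhabitats Microhabitat labels used to check the even split
#'   (taken from the design's attribute when present).
#' @return A list with `rows` (the design with a `total_seeds` column),
#'   `n_packets` and `n_seeds` grand totals.
#' @examples
#' allocationTotals(eriophyllumDesign())$n_seeds  # 4860
#' @export
allocationTotals <- function(design,
                             microhabitats = attr(design, "microhabitats")) {
  stopifnot(is.data.frame(design),
            all(c("n_packets", "seeds_per_packet") %in% names(design) |
                  nrow(design) == 0L))
  if (nrow(design) == 0L)
    return(list(rows = design, n_packets = 0L, n_seeds = 0L))
  stopifnot(all(design$n_packets >= 0), all(design$seeds_per_packet >= 0))
  if (!is.null(microhabitats) &&
      identical(attr(design, "split_rule"), "even") &&
      any(design$n_packets %% length(microhabitats) != 0L))
    stop("even split rule: n_packets must be divisible by the number of ",
         "microhabitats in every design row", call. = FALSE)
  rows <- design
  rows$total_seeds <- design$n_packets * design$seeds_per_packet
  list(rows = rows,
       n_packets = as.integer(sum(design$n_packets)),
       n_seeds = as.integer(sum(rows$total_seeds)))
}
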