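# required columns of the clone-record table; compartment-specific distance
# columns are checked per row
.clone_cols <- c("clone_id", "mouse_id", "time_days", "size_eighths",
                 "compartment")
.compartments <- c("control", "intra_tumour", "adjacent")

.validate_records <- function(records, where = "clone table") {
  missing <- setdiff(.clone_cols, names(records))
  if (length(missing)) {
    stop(where, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$size_eighths %in% 1:8)
  if (length(bad)) {
    stop(where, ": size_eighths outside 1..8 at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$compartment %in% .compartments)
  if (length(bad)) {
    stop(where, ": unknown compartment at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$compartment == "adjacent" &
                 (is.na(records$dist_edge_cd) | records$dist_edge_cd < 0))
  if (length(bad)) {
    stop(where, ": adjacent records need a non-negative dist_edge_cd; ",
         "row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(records$compartment == "intra_tumour" &
                 (is.na(records$dist_centre_um) |
                    records$dist_centre_um < 0))
  if (length(bad)) {
    stop(where, ": intra-tumour records need a non-negative ",
         "dist_centre_um; row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Read a clone-record table
#'
#' Reads the tab-delimited clone table (UTF-8, header required): one row per
#' traced clone with columns `clone_id`, `mouse_id`, `time_days`,
#' `size_eighths`, `compartment` (`control`, `intra_tumour` or `adjacent`)
#' and the compartment-appropriate spatial columns `dist_edge_cd`,
#' `dist_centre_um`, `tumour_id`, `tumour_area_um2`, `crypt_diameter_um`.
#' Unknown columns are preserved. Validation errors name the offending row.
#'
#' @param path Path to a TSV file.
#' @return A validated clone-record `data.frame`.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.delim(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
  for (col in c("dist_edge_cd", "dist_centre_um", "tumour_area_um2",
                "crypt_diameter_um")) {
    if (!is.null(records[[col]])) records[[col]] <- as.numeric(records[[col]])
  }
  .validate_records(records, where = basename(path))
}

#' Write a clone-record table
#'
#' @param records Clone-record `data.frame` (validated before writing).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(records, path) {
  .validate_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Clone-size prevalence by time point
#'
#' Converts eighths-binned counts into per-time proportions, the tabular
#' form behind clone-size prevalence heatmaps: each row is a time point,
#' sums to 1, and its maximum marks the most prevalent clone size.
#'
#' @param counts A [clone_counts()] object.
#' @return A `data.frame` with `time_days` and proportion columns
#'   `eighth_1` .. `eighth_8`.
#' @export
size_prevalence_table <- function(counts) {
  stopifnot(inherits(counts, "clone_counts"))
  tot <- rowSums(counts$counts)
  keep <- tot > 0
  if (!all(keep)) {
    warning("omitting time point(s) with no clones: ",
            paste(counts$times[!keep], collapse = ", "), call. = FALSE)
  }
  prop <- counts$counts[keep, , drop = FALSE] / tot[keep]
  out <- data.frame(time_days = counts$times[keep], prop)
  names(out) <- c("time_days", paste0("eighth_", 1:8))
  rownames(out) <- NULL
  out
}

#' Derive a named sub-seed from a top-level seed
#'
#' All randomness in a multi-stage pipeline flows from one top-level seed;
#' each stage uses a deterministic sub-seed derived from the seed and the
#' stage name, so stages are reproducible independently and do not share
#' streams.
#'
#' @param seed Integer top-level seed.
#' @param name Character stage name.
#' @return An integer seed in `0 .. 2^31 - 2`.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 69069 + h) %% (2^31 - 1))
}
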