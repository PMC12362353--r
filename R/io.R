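# File formats, table merging, and run manifests.
#
# Climate is exchanged as long-form CSV (cell, date, t, rh); clusters,
# births, exposures and regression tables as CSV; truth parameters, fit
# results and manifests as JSON. CSV dialect: UTF-8, comma, header row, no
# index column. Dates are ISO-8601.

#' Read a daily climate table from long-form CSV
#'
#' Validates the schema (`cell`, `date`, `t`, `rh`), unit ranges (`rh` in
#' \[0, 100\]) and that every cell has a complete daily calendar between its
#' first and last date; gaps are reported by date.
#'
#' @param path CSV file with columns `cell`, `date` (ISO-8601), `t` (deg C),
#'   `rh` (percent).
#' @return A `data.table(cell, date, t, rh)`.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path, call. = FALSE)
  d <- data.table::fread(path)
  need <- c("cell", "date", "t", "rh")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("climate file missing variable(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d[, date := as.Date(date)]
  if (anyNA(d$date)) stop("unparseable dates in climate file", call. = FALSE)
  if (anyNA(d$t) || anyNA(d$rh)) stop("missing temperature/humidity values", call. = FALSE)
  if (any(d$rh < 0 | d$rh > 100)) stop("relative humidity outside [0, 100]", call. = FALSE)
  gaps <- d[, {
    full <- seq(min(date), max(date), by = "day")
    list(missing = as.character(full[!full %in% date]))
  }, by = "cell"]
  if (nrow(gaps)) {
    stop(sprintf("climate calendar incomplete: cell %s missing %s%s",
                 gaps$cell[1], gaps$missing[1],
                 if (nrow(gaps) > 1) sprintf(" (and %d more gaps)", nrow(gaps) - 1L) else ""),
         call. = FALSE)
  }
  data.table::setkeyv(d, c("cell", "date"))
  d[]
}

#' Write a daily climate table to long-form CSV
#' @param climate `data.table(cell, date, t, rh)`.
#' @param path Output path.
#' @export
write_climate <- function(climate, path) {
  stopifnot(all(c("cell", "date", "t", "rh") %in% names(climate)))
  data.table::fwrite(climate[, c("cell", "date", "t", "rh"), with = FALSE], path)
  invisible(path)
}

#' Merge births, exposures and clusters into the analysis table
#'
#' Inner join with key-integrity checks: every exposure row must match
#' exactly one birth (duplicate keys are an error), and cluster attributes
#' (country, cell ids, residence type) are attached. The join-loss report
#' (births without exposure, etc.) is attached as attribute `join_loss`.
#'
#' @param births,exposures Keyed by `birth_id`.
#' @param clusters Keyed by `cluster_id`.
#' @return The merged `data.table`.
#' @export
merge_tables <- function(births, exposures, clusters) {
  for (nm in c("births", "exposures")) {
    tab <- get(nm)
    if (anyDuplicated(tab$birth_id)) stop("duplicate birth_id in ", nm, call. = FALSE)
  }
  if (anyDuplicated(clusters$cluster_id)) stop("duplicate cluster_id in clusters", call. = FALSE)
  keep <- intersect(c("cluster_id", "country", "cell", "pcell", "cell1", "cell2",
                      "residence_type", "lon", "lat"), names(clusters))
  m <- merge(births, exposures, by = "birth_id")
  m <- merge(m, clusters[, keep, with = FALSE], by = "cluster_id")
  loss <- list(
    births_in = nrow(births),
    births_without_exposure = nrow(births) - length(intersect(births$birth_id, exposures$birth_id)),
    exposures_without_birth = nrow(exposures) - length(intersect(births$birth_id, exposures$birth_id)),
    births_without_cluster = nrow(births) - sum(births$cluster_id %in% clusters$cluster_id),
    rows_out = nrow(m))
  data.table::setkeyv(m, "birth_id")
  data.table::setattr(m, "join_loss", loss)
  m[]
}

#' Build a run manifest
#'
#' Records the package version, seeds, per-stage row/reject counts, and an
#' md5 checksum for every listed file, so a study run is fully determined by
#' its manifest.
#'
#' @param files Character vector of output file paths.
#' @param seeds Named list/vector of seeds used.
#' @param counts Named list of row and reject counts per stage.
#' @return A manifest list (class `run_manifest`).
#' @export
run_manifest <- function(files = character(0), seeds = list(), counts = list()) {
  files <- files[file.exists(files)]
  structure(list(
    tool = paste0("heatnatal ", as.character(utils::packageVersion("heatnatal"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds, counts = counts,
    files = if (length(files))
      data.frame(path = files, md5 = unname(tools::md5sum(files)),
                 row.names = NULL) else NULL),
    class = "run_manifest")
}

#' Write / read a manifest (lossless JSON round trip)
#' @param manifest A [run_manifest()].
#' @param path JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "run_manifest")
}
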