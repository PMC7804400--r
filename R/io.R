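#' Read and write qPCR plate-export tables
#'
#' Plate tables use the instrument-export CSV dialect with header
#' `plate_id,well,sample_id,assay_id,replicate,ct_fam,ct_vic`. A
#' reaction that never crossed threshold is encoded as the literal token
#' `"Undetermined"` on disk and carried as `NA` in R.
#'
#' @param wells tibble of plate wells.
#' @param path file path.
#' @return `read_plate_csv()` returns a tibble; `write_plate_csv()`
#'   returns `path` invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  out <- as.data.frame(wells)
  for (col in c("ct_fam", "ct_vic")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "Undetermined", format(v, digits = 15))
  }
  names(out)[names(out) == "replicate"] <- "replicate"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  parse_ct <- function(v) {
    v[v %in% c("Undetermined", "undetermined", "UNDETERMINED", "")] <- NA
    as.numeric(v)
  }
  tibble::tibble(
    plate_id = raw$plate_id, well = raw$well,
    sample_id = raw$sample_id, assay_id = raw$assay_id,
    replicate = as.integer(raw$replicate),
    ct_fam = parse_ct(raw$ct_fam), ct_vic = parse_ct(raw$ct_vic)
  )
}

#' Read and write sample metadata tables
#'
#' Sample metadata is CSV with columns
#' `sample_id,donor_id,tissue,material,diagnosis`.
#' @param meta tibble of sample metadata.
#' @param path file path.
#' @export
write_meta_csv <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_meta_csv
#' @export
read_meta_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Save or load a simulation configuration as YAML
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
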