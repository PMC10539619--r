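# Export of a recording model to an HDF5 file laid out along the NIX data
# model: a root with "data" and "metadata" groups, one block per recording,
# and one data array per trace / event series / spike series, each with
# typed dimension descriptors. Entity ids are deterministic (derived from
# entity names), and no wall-clock timestamps are written, so repeated
# exports of the same model are identical.

nix_id <- function(name) {
  # FNV-1a over the UTF-8 bytes; stable, dependency-free entity ids
  bytes <- utf8ToInt(enc2utf8(name))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2147483648), b) * 16777619) %% 4294967296
  sprintf("nix-%08x-%04x", as.integer(h %% 2147483648), length(bytes) %% 65536)
}

nix_group_name <- function(name) gsub("/", " - ", name, fixed = TRUE)

nix_entity_attrs <- function(loc, name, type) {
  rhdf5::h5writeAttribute(name, loc, "name")
  rhdf5::h5writeAttribute(type, loc, "type")
  rhdf5::h5writeAttribute(nix_id(paste(type, name)), loc, "id")
  rhdf5::h5writeAttribute("1970-01-01T00:00:00", loc, "created_at")
  rhdf5::h5writeAttribute("1970-01-01T00:00:00", loc, "updated_at")
}

write_f32_dataset <- function(fid, path, values) {
  rhdf5::h5createDataset(fid, path, dims = length(values),
                         H5type = "H5T_IEEE_F32LE", level = 0L)
  rhdf5::h5write(values, fid, path)
}

#' Export a recording model to NIX-structured HDF5
#'
#' Serializes a [dps_convert()] result into a single HDF5 file following
#' the NIX data-model conventions: root attributes identifying the format,
#' a `data` group holding one block for the recording, and under the
#' block's `data_arrays` one array per component. Regularly sampled traces
#' store their samples as 32-bit floats (the precision of the source
#' format) with a sampled dimension carrying `sampling_interval` and
#' `offset` in seconds; irregular traces use a range dimension with
#' explicit tick times. Event series store event times with their labels in
#' a companion `labels` dataset; spike series store the recognized spike
#' times with the entered times in a companion `entered_times` dataset. The
#' source file's footer string is kept in the block's metadata section.
#'
#' Exports are deterministic: entity ids are content-derived and the
#' timestamp attributes are fixed to the epoch, so identical models produce
#' identical files.
#'
#' @param model a `dps_recording`.
#' @param path output path of the HDF5 file.
#' @return `path`, invisibly.
#' @export
#' @examples
#' ses <- generate_session(session_spec(duration_s = 0.05, seed = 1))
#' h5 <- tempfile(fileext = ".nix.h5")
#' export_nix_h5(dps_convert(ses$file), h5)
#' rhdf5::h5ls(h5, recursive = FALSE)
export_nix_h5 <- function(model, path) {
  stopifnot(inherits(model, "dps_recording"))
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) dps_abort("io_failure", sprintf("cannot create HDF5 file at %s", path))
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5writeAttribute("nix", fid, "format")
  rhdf5::h5writeAttribute(c(1L, 2L, 1L), fid, "version")
  rhdf5::h5writeAttribute(nix_id(model$provenance), fid, "id")
  rhdf5::h5writeAttribute("1970-01-01T00:00:00", fid, "created_at")
  rhdf5::h5writeAttribute("1970-01-01T00:00:00", fid, "updated_at")

  rhdf5::h5createGroup(fid, "data")
  rhdf5::h5createGroup(fid, "metadata")
  block <- "data/recording"
  rhdf5::h5createGroup(fid, block)
  gid <- rhdf5::H5Gopen(fid, block)
  nix_entity_attrs(gid, "recording", "nix.block")
  rhdf5::H5Gclose(gid)
  arrays <- paste0(block, "/data_arrays")
  rhdf5::h5createGroup(fid, arrays)

  new_array <- function(name, type) {
    g <- paste0(arrays, "/", nix_group_name(name))
    rhdf5::h5createGroup(fid, g)
    gid <- rhdf5::H5Gopen(fid, g)
    nix_entity_attrs(gid, name, type)
    rhdf5::H5Gclose(gid)
    rhdf5::h5createGroup(fid, paste0(g, "/dimensions"))
    g
  }

  for (tr in model$traces) {
    g <- new_array(tr$name, "nix.data_array")
    write_f32_dataset(fid, paste0(g, "/data"), tr$samples)
    d1 <- paste0(g, "/dimensions/1")
    rhdf5::h5createGroup(fid, d1)
    did <- rhdf5::H5Gopen(fid, d1)
    if (!is.null(tr$sampling_interval_s)) {
      rhdf5::h5writeAttribute("sample", did, "dimension_type")
      rhdf5::h5writeAttribute(tr$sampling_interval_s, did, "sampling_interval")
      rhdf5::h5writeAttribute(tr$start_time_s, did, "offset")
    } else {
      rhdf5::h5writeAttribute("range", did, "dimension_type")
      rhdf5::h5write(tr$times_s, fid, paste0(d1, "/ticks"))
    }
    rhdf5::h5writeAttribute("s", did, "unit")
    rhdf5::H5Gclose(did)
  }

  for (ev in model$events) {
    name <- if (nrow(ev) > 0 || length(ev$name) > 0) (ev$name[1] %||% "events") else "events"
    if (is.na(name)) name <- "events"
    g <- new_array(name, "nix.data_array")
    rhdf5::h5write(as.double(ev$time), fid, paste0(g, "/data"))
    if (nrow(ev) > 0) rhdf5::h5write(as.character(ev$label), fid, paste0(g, "/labels"))
    d1 <- paste0(g, "/dimensions/1")
    rhdf5::h5createGroup(fid, d1)
    did <- rhdf5::H5Gopen(fid, d1)
    rhdf5::h5writeAttribute("set", did, "dimension_type")
    rhdf5::h5writeAttribute("s", did, "unit")
    rhdf5::H5Gclose(did)
  }

  for (sp in model$spikes) {
    name <- sp$track_name[1] %||% "spikes"
    if (is.na(name)) name <- "spikes"
    g <- new_array(name, "nix.data_array")
    rhdf5::h5write(as.double(sp$recognized_time), fid, paste0(g, "/data"))
    rhdf5::h5write(as.double(sp$entered_time), fid, paste0(g, "/entered_times"))
    d1 <- paste0(g, "/dimensions/1")
    rhdf5::h5createGroup(fid, d1)
    did <- rhdf5::H5Gopen(fid, d1)
    rhdf5::h5writeAttribute("set", did, "dimension_type")
    rhdf5::h5writeAttribute("s", did, "unit")
    rhdf5::H5Gclose(did)
  }

  meta <- "metadata/recording"
  rhdf5::h5createGroup(fid, meta)
  mid <- rhdf5::H5Gopen(fid, meta)
  nix_entity_attrs(mid, "recording", "nix.section")
  rhdf5::h5writeAttribute(model$provenance, mid, "provenance")
  rhdf5::H5Gclose(mid)

  invisible(path)
}

#' List the data arrays of an exported NIX/HDF5 file
#'
#' Small read-back helper: returns one row per data array under the
#' recording block, with its dimension type and element count. Useful for
#' checking an export without NIX-specific tooling.
#'
#' @param path path of a file written by [export_nix_h5()].
#' @return a tibble with columns `name`, `dimension_type`, `n`.
#' @export
nix_contents <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  listing <- rhdf5::h5ls(path)
  base <- "/data/recording/data_arrays"
  groups <- listing$name[listing$group == base & listing$otype == "H5I_GROUP"]
  rows <- lapply(groups, function(g) {
    gpath <- paste0(base, "/", g)
    att <- rhdf5::h5readAttributes(path, gpath)
    d1 <- paste0(gpath, "/dimensions/1")
    datt <- tryCatch(rhdf5::h5readAttributes(path, d1), error = function(e) list())
    data <- rhdf5::h5read(path, paste0(gpath, "/data"))
    tibble::tibble(name = as.character(att$name %||% g),
                   dimension_type = as.character(datt$dimension_type %||% NA_character_),
                   n = length(data))
  })
  if (length(rows) == 0L)
    return(tibble::tibble(name = character(), dimension_type = character(), n = integer()))
  dplyr::bind_rows(rows)
}
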