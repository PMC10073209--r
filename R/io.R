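# metadata header lines written at the top of every CSV output
meta_header <- function(seed = NA, config_hash = NA) {
  version <- as.character(utils::packageVersion("rtmscoil"))
  c(sprintf("# rtmscoil %s", version),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# seed: %s", seed))
}

write_csv_with_meta <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_with_meta <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# md5 of the JSON serialization of an R object (config provenance);
# S3 classes are stripped so nested spec/phantom objects serialize
config_hash <- function(obj) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(strip(obj), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a field map as long-format CSV
#'
#' Columns `x_mm`, `y_mm`, `B_T`, preceded by comment metadata lines
#' (package version, config hash, seed).
#'
#' @param map a [field_map_on_plane()] result.
#' @param path output path.
#' @param seed,config_hash provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(map, path, seed = NA, config_hash = NA) {
  stopifnot(inherits(map, "field_map"))
  df <- expand.grid(x_mm = map$x_mm, y_mm = map$y_mm)
  df$B_T <- as.vector(map$values)
  write_csv_with_meta(df, path, seed, config_hash)
}

#' Write a distance sweep as CSV
#'
#' Columns `distance_mm`, `peak_B_T` with metadata header lines.
#'
#' @param sweep a [distance_sweep()] result.
#' @inheritParams write_field_map
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, seed = NA, config_hash = NA) {
  stopifnot(inherits(sweep, "distance_sweep"))
  write_csv_with_meta(as.data.frame(sweep), path, seed, config_hash)
}

#' Write an induced E-field profile as CSV
#'
#' Columns `depth_mm`, `E_V_per_m`, `ring_radius_mm`.
#'
#' @param profile an [induced_efield()] result.
#' @inheritParams write_field_map
#' @return `path`, invisibly.
#' @export
write_efield_profile <- function(profile, path, seed = NA,
                                 config_hash = NA) {
  stopifnot(inherits(profile, "efield_profile"))
  write_csv_with_meta(as.data.frame(profile), path, seed, config_hash)
}
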