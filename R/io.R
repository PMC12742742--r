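# Plain-text readers and writers for every pipeline stage. Generators write
# the same dialects the analysis stages read, so files round-trip.

read_table_auto <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    read.delim(path, stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

write_table_auto <- function(x, path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write a mutation table
#'
#' Columns: `gene`, `population`, `level`, `mutation_id`, `frequency`
#' (CSV or TSV by extension).
#'
#' @param path file path.
#' @return validated mutation table.
#' @export
read_mutation_table <- function(path) validate_mutations(read_table_auto(path))

#' @rdname read_mutation_table
#' @param data mutation table to write.
#' @export
write_mutation_table <- function(data, path) {
  write_table_auto(validate_mutations(data), path)
}

#' Read a TCS catalog from component and regulon tables
#'
#' @param components_path table with columns `tcs`, `gene`, `role`.
#' @param regulon_path table with columns `tcs`, `target`, `cc`, `bp`.
#' @return a [tcs_catalog()].
#' @export
read_tcs_catalog <- function(components_path, regulon_path) {
  tcs_catalog(read_table_auto(components_path), read_table_auto(regulon_path))
}

#' Write a TCS catalog
#'
#' @param catalog a [tcs_catalog()].
#' @param components_path,regulon_path output paths.
#' @export
write_tcs_catalog <- function(catalog, components_path, regulon_path) {
  stopifnot(inherits(catalog, "tcs_catalog"))
  write_table_auto(catalog$components, components_path)
  write_table_auto(catalog$regulon, regulon_path)
  invisible(c(components_path, regulon_path))
}

#' Write a ranked TCS priority table
#'
#' @param result a [priority_rank()] result.
#' @param path output path (TSV/CSV by extension).
#' @export
write_priority_table <- function(result, path) {
  write_table_auto(as.data.frame(result), path)
}

#' Read / write a long-format reporter table
#'
#' Long dialect: columns `time`, `role` (`"sample"`/`"blank"`), `f`, `od`.
#'
#' @param path file path.
#' @return a [reporter_series()].
#' @export
read_reporter_series <- function(path) {
  d <- read_table_auto(path)
  need <- c("time", "role", "f", "od")
  if (length(setdiff(need, names(d))))
    stop_config("reporter table needs columns: ", paste(need, collapse = ", "))
  s <- d[d$role == "sample", ]
  b <- d[d$role == "blank", ]
  s <- s[order(s$time), ]; b <- b[order(b$time), ]
  if (!identical(s$time, b$time))
    stop_config("sample and blank rows must cover the same time points")
  reporter_series(s$time, s$f, b$f, s$od, b$od)
}

#' @rdname read_reporter_series
#' @param series a [reporter_series()] to write.
#' @export
write_reporter_series <- function(series, path) {
  long <- rbind(
    data.frame(time = series$time, role = "sample", f = series$f_sample,
               od = series$od_sample),
    data.frame(time = series$time, role = "blank", f = series$f_blank,
               od = series$od_blank))
  write_table_auto(long, path)
}

#' Read / write a protein quantification matrix
#'
#' Wide dialect: a TSV/CSV with columns `protein`, `proteotypic`
#' (TRUE/FALSE), `qvalue`, then one log2-intensity column per sample (`NA`
#' cells are missing values), plus a two-column group map (`sample`,
#' `group`).
#'
#' @param matrix_path,groups_path file paths.
#' @return a [protein_quant()].
#' @export
read_protein_matrix <- function(matrix_path, groups_path) {
  d <- read_table_auto(matrix_path)
  gm <- read_table_auto(groups_path)
  need <- c("protein", "proteotypic", "qvalue")
  if (length(setdiff(need, names(d))))
    stop_config("protein matrix needs columns: ", paste(need, collapse = ", "))
  samp <- setdiff(names(d), need)
  m <- as.matrix(d[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$protein
  groups <- gm$group[match(samp, gm$sample)]
  if (anyNA(groups)) stop_config("group map does not cover all sample columns")
  protein_quant(m, groups, proteotypic = d$proteotypic, qvalue = d$qvalue)
}

#' @rdname read_protein_matrix
#' @param x a [protein_quant()] to write.
#' @export
write_protein_matrix <- function(x, matrix_path, groups_path) {
  stopifnot(inherits(x, "protein_quant"))
  d <- data.frame(protein = rownames(x$intensity), proteotypic = x$proteotypic,
                  qvalue = x$qvalue, x$intensity, check.names = FALSE)
  write_table_auto(d, matrix_path)
  write_table_auto(data.frame(sample = colnames(x$intensity), group = x$groups),
                   groups_path)
  invisible(c(matrix_path, groups_path))
}

#' Read / write an 8-bit grayscale plate image as PNG
#'
#' @param path PNG path.
#' @return numeric matrix of gray levels 0-255.
#' @export
read_spot_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- rgb_to_gray(a[, , 1:3] * 255) / 255
  round(a * 255)
}

#' @rdname read_spot_png
#' @param img numeric matrix with gray levels in `[0, 255]`.
#' @export
write_spot_png <- function(img, path) {
  png::writePNG(pmin(pmax(round(img), 0), 255) / 255, path)
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml_load_file(path)
  do.call(simulation_config, y)
}

#' @rdname read_simulation_config
#' @param config a [simulation_config()] to write.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml_write_file(unclass(config), path)
  invisible(path)
}

# thin indirection so the yaml dependency stays optional at load time
yaml_load_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config("the 'yaml' package is required to read YAML configurations")
  yaml::read_yaml(path)
}

yaml_write_file <- function(x, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config("the 'yaml' package is required to write YAML configurations")
  yaml::write_yaml(x, path)
}
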