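# ---------------------------------------------------------------------------
# Readers/writers (TSV with '.' decimal and NA for missing, GMT gene sets,
# JSON config/manifest) and the run manifest.
# ---------------------------------------------------------------------------

# fread for speed on plain files; gzip handled through a connection.
read_tsv_table <- function(path) {
  if (grepl("\\.gz$", path)) {
    utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      check.names = FALSE)
  }
}

#' Read an expression matrix from TSV
#'
#' First column probe id, header row of sample ids; gzip transparently
#' accepted. Errors on duplicate probe ids and non-numeric cells.
#'
#' @param path TSV(.gz) path.
#' @return Probes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  dt <- read_tsv_table(path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric expression cells in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param expr Probes x samples matrix; \code{path} output path.
#' @param path Output path.
#' @param id_column Header of the probe-id column (default "probe_id").
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path, id_column = "probe_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Header must contain \code{sample_id}; extra columns are preserved.
#'
#' @param path TSV(.gz) path.
#' @param required Further column names that must be present (e.g. the
#'   trait to analyse).
#' @return Data frame, one row per sample.
#' @export
read_phenotypes <- function(path, required = character(0)) {
  df <- read_tsv_table(path)
  need <- unique(c("sample_id", required))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' Write gene sets as GMT lines
#'
#' One line per set: name, description, then the probe ids, tab-separated.
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default "famnet").
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "famnet"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a module partition as two-column TSV
#' @param partition Named probe -> label vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(probe_id = names(partition),
                                module_label = as.character(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis artifacts with a checksummed manifest
#'
#' Writes every table/artifact it is given into \code{outdir} and a
#' \code{manifest.json} listing files, md5 checksums, the run
#' configuration, the seed and any error notes, so a rerun can be verified
#' byte for byte.
#'
#' @param outdir Output directory (created if absent).
#' @param artifacts Named list; data frames become TSV, named lists of
#'   character vectors become GMT, character vectors become plain text.
#' @param config List echoed into the manifest.
#' @param seed Integer seed echoed into the manifest.
#' @param errors Character vector of error notes from partial failures.
#' @return The manifest, invisibly.
#' @export
write_results <- function(outdir, artifacts, config = list(), seed = NA,
                          errors = character(0)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    f <- if (is.data.frame(a)) {
      fp <- file.path(outdir, paste0(nm, ".tsv"))
      utils::write.table(a, fp, sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "NA")
      fp
    } else if (is.list(a)) {
      fp <- file.path(outdir, paste0(nm, ".gmt"))
      write_gmt(a, fp)
      fp
    } else {
      fp <- file.path(outdir, paste0(nm, ".txt"))
      writeLines(as.character(a), fp)
      fp
    }
    files <- c(files, f)
  }
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))),
    config = config, seed = seed, errors = as.list(errors),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("famnet")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
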