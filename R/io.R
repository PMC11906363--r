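#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Write variants as a minimal VCF (v4.2, sites-only)
#'
#' @param variants data.frame with `chrom, pos, ref, alt` (an `id` column is
#'   used if present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simple_vcf <- function(variants, path) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt"), "variants")
  header <- c("##fileformat=VCFv4.2",
              "##source=secondhit",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  id <- if ("id" %in% names(variants)) as.character(variants$id) else "."
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$chrom, as.integer(variants$pos), id,
                  variants$ref, variants$alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sites from a VCF or TSV variant file
#'
#' VCF files (by extension `.vcf`) are parsed with `vcfR` when available and
#' with a minimal fixed-column reader otherwise; anything else is read as a
#' TSV with `chrom, pos, ref, alt` columns.
#'
#' @param path Input path.
#' @return data.frame `chrom, pos, ref, alt`.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (requireNamespace("vcfR", quietly = TRUE)) {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- vcfR::getFIX(v)
      return(data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE))
    }
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    return(data.frame(
      chrom = vapply(parts, `[[`, character(1), 1),
      pos = as.integer(vapply(parts, `[[`, character(1), 2)),
      ref = vapply(parts, `[[`, character(1), 4),
      alt = vapply(parts, `[[`, character(1), 5),
      stringsAsFactors = FALSE))
  }
  read_tsv(path)
}

#' Write a cohort configuration to JSON (or YAML)
#' @param config Cohort configuration list.
#' @param path Output path; `.yaml`/`.yml` selects YAML.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  # named numeric vectors must serialize as objects, not unboxed scalars
  listify <- function(ind) {
    ind$samples <- lapply(ind$samples, function(s) {
      s$clone_fractions <- as.list(s$clone_fractions)
      s
    })
    ind
  }
  config$proband <- listify(config$proband)
  config$controls <- lapply(config$controls, listify)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort configuration from JSON (or YAML)
#' @param path Input path.
#' @return Configuration list (validated).
#' @export
read_cohort_config <- function(path) {
  config <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
  # JSON round-trip turns named numeric vectors into lists; restore them
  fix_samples <- function(ind) {
    ind$samples <- lapply(ind$samples, function(s) {
      cf <- unlist(s$clone_fractions)
      s$clone_fractions <- stats::setNames(as.numeric(cf), names(cf))
      for (fld in c("tumor_contamination", "target_depth", "error_rate")) {
        if (!is.null(s[[fld]])) s[[fld]] <- as.numeric(s[[fld]])
      }
      s
    })
    ind$parents <- unlist(ind$parents)
    ind
  }
  config$proband <- fix_samples(config$proband)
  config$controls <- lapply(config$controls, fix_samples)
  config$genome$chroms <- unlist(config$genome$chroms)
  validate_cohort_config(config)
  config
}
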