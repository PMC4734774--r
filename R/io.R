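#' Read a somatic mutation table (MAF-dialect TSV or minimal VCF)
#'
#' Normalizes per-variant input into the mutation-table layout used by the
#' fitting pipeline: one row per variant with a `sample` id and an
#' `observed_allele_fraction`, computed from alt/ref (or alt/depth) read
#' counts when no fraction column is present. Column names can be remapped
#' through `column_map` for MAF dialects. VCF input (uncompressed v4.x with
#' an `AD` genotype field) is parsed with the vcfR package.
#'
#' @param path Path to the file.
#' @param format `"maf"` (tab-separated, with header) or `"vcf"`.
#' @param column_map Named character vector mapping the canonical names
#'   `sample`, `allele_fraction`, `t_alt_count`, `t_ref_count`, `t_depth`
#'   to the file's column names, e.g.
#'   `c(sample = "Tumor_Sample_Barcode")`. Only needed when names differ.
#' @return A data.frame with columns `sample`,
#'   `observed_allele_fraction` and whichever count columns were present;
#'   attribute `"n_skipped"` counts rows dropped for unparsable values.
#' @export
read_mutation_table <- function(path, format = c("maf", "vcf"),
                                column_map = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") return(read_vcf_table(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) <= 1L)
    stop("schema error: no parsable rows/columns in ", path, call. = FALSE)
  canon <- c("sample", "allele_fraction", "t_alt_count", "t_ref_count",
             "t_depth")
  # standard MAF spellings recognized out of the box
  maf_alias <- c(sample = "Tumor_Sample_Barcode", allele_fraction = "i_tumor_f")
  for (nm in names(maf_alias))
    if (!nm %in% names(raw) && maf_alias[[nm]] %in% names(raw))
      names(raw)[names(raw) == maf_alias[[nm]]] <- nm
  for (nm in names(column_map))
    if (column_map[[nm]] %in% names(raw))
      names(raw)[names(raw) == column_map[[nm]]] <- nm
  if (!"sample" %in% names(raw))
    stop("schema error: missing required column(s): sample",
         " (map it via `column_map`)", call. = FALSE)
  has_af <- "allele_fraction" %in% names(raw)
  has_counts <- "t_alt_count" %in% names(raw) &&
    ("t_ref_count" %in% names(raw) || "t_depth" %in% names(raw))
  if (!has_af && !has_counts)
    stop("schema error: need either `allele_fraction` or `t_alt_count` ",
         "plus `t_ref_count`/`t_depth`", call. = FALSE)
  if (has_af) {
    af <- as.numeric(raw$allele_fraction)
  } else {
    alt <- as.numeric(raw$t_alt_count)
    tot <- if ("t_depth" %in% names(raw)) as.numeric(raw$t_depth)
           else alt + as.numeric(raw$t_ref_count)
    af <- alt / tot
  }
  ok <- is.finite(af) & af >= 0 & af <= 1 & !is.na(raw$sample)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message("read_mutation_table: skipped ", n_skipped, " unparsable row(s)")
  out <- raw[ok, intersect(canon, names(raw)), drop = FALSE]
  out$observed_allele_fraction <- af[ok]
  attr(out, "n_skipped") <- n_skipped
  out
}

read_vcf_table <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || nrow(ad) == 0L)
    stop("schema error: VCF has no AD genotype field", call. = FALSE)
  rows <- lapply(colnames(ad), function(smp) {
    parts <- strsplit(ad[, smp], ",", fixed = TRUE)
    ref <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    data.frame(sample = smp, t_ref_count = ref, t_alt_count = alt)
  })
  out <- do.call(rbind, rows)
  af <- out$t_alt_count / (out$t_alt_count + out$t_ref_count)
  ok <- is.finite(af)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message("read_mutation_table: skipped ", n_skipped, " unparsable row(s)")
  out <- out[ok, , drop = FALSE]
  out$observed_allele_fraction <- af[ok]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write result records with a provenance header
#'
#' Writes a data.frame as CSV (with `#`-prefixed provenance comment lines:
#' package version, seed, config hash) or as JSON (provenance embedded).
#' Floats are written at 12 significant digits, so a write/read round trip
#' preserves values to numerical relevance.
#'
#' @param records A data.frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param seed Seed to record in the provenance header (or `NA`).
#' @param config Optional list recorded (hashed for CSV) in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json"),
                          seed = NA, config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  prov <- list(package = "passengr",
               version = as.character(utils::packageVersion("passengr")),
               seed = seed,
               config_hash = if (is.null(config)) NA_character_
                             else digest_config(config))
  if (format == "json") {
    jsonlite::write_json(list(provenance = prov, records = records), path,
                         auto_unbox = TRUE, digits = 12, na = "null")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(prov),
                     vapply(prov, function(x) format(x), character(1L))),
             con)
  num <- vapply(records, is.double, logical(1L))
  records[num] <- lapply(records[num], signif, digits = 12L)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path Path to the CSV.
#' @return The records data.frame; provenance lines are exposed as the
#'   `"provenance"` attribute.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  out <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  attr(out, "provenance") <- sub("^# ", "", prov)
  out
}

digest_config <- function(config) {
  # small stable hash of the serialized config; no external digest dependency
  bytes <- serialize(config, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(bytes) * (seq_along(bytes) %% 251)) %%
            .Machine$integer.max)
}
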