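#' Construct a GWAS summary-statistics table
#'
#' A `gwas_table` is the unit of all summary-level input and output: one
#' trait's per-SNP association statistics. It is a `data.frame` with the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `ncase`, `ncontrol`
#' (the last six may be `NA` where optional) plus `trait_name` and
#' `trait_type` attributes.
#'
#' Effect sizes are per copy of the effect allele: log odds ratios for
#' binary traits, standard-deviation units for quantitative traits.
#'
#' @param records data.frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`. Optional: `chrom`, `pos`, `eaf`,
#'   `n`, `ncase`, `ncontrol`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param validate drop invalid rows (non-ACGT alleles, `se <= 0`,
#'   `pval` outside (0, 1], missing `beta`/`se`/`pval`, duplicated rsIDs)
#'   and attach a validation report? If `FALSE` the rows are taken as-is.
#' @return A `gwas_table`; attribute `validation` holds the drop counts.
#' @export
gwas_table <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                       validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  req <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("gwas_table: missing required columns: ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    snp_id = as.character(records$snp_id),
    chrom = if ("chrom" %in% names(records)) as.character(records$chrom) else NA_character_,
    pos = if ("pos" %in% names(records)) as.integer(records$pos) else NA_integer_,
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele = toupper(as.character(records$other_allele)),
    eaf = if ("eaf" %in% names(records)) as.numeric(records$eaf) else NA_real_,
    beta = as.numeric(records$beta),
    se = as.numeric(records$se),
    pval = as.numeric(records$pval),
    n = if ("n" %in% names(records)) as.numeric(records$n) else NA_real_,
    ncase = if ("ncase" %in% names(records)) as.numeric(records$ncase) else NA_real_,
    ncontrol = if ("ncontrol" %in% names(records)) as.numeric(records$ncontrol) else NA_real_,
    stringsAsFactors = FALSE
  )

  report <- c(n_input = nrow(out), bad_stat = 0L, bad_allele = 0L,
              bad_eaf = 0L, duplicate_snp = 0L, n_kept = nrow(out))
  if (validate) {
    acgt <- c("A", "C", "G", "T")
    bad_stat <- is.na(out$beta) | is.na(out$se) | is.na(out$pval) |
      out$se <= 0 | out$pval <= 0 | out$pval > 1
    bad_allele <- !(out$effect_allele %in% acgt) | !(out$other_allele %in% acgt) |
      out$effect_allele == out$other_allele
    # multi-allelic rsIDs (duplicated snp_id) are rejected entirely
    dup <- out$snp_id %in% out$snp_id[duplicated(out$snp_id)]
    bad_eaf <- !is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1)
    out$eaf[bad_eaf] <- NA_real_  # out-of-range frequency treated as missing
    drop <- bad_stat | bad_allele | dup
    report["bad_stat"] <- sum(bad_stat)
    report["bad_allele"] <- sum(bad_allele & !bad_stat)
    report["duplicate_snp"] <- sum(dup & !bad_stat & !bad_allele)
    report["bad_eaf"] <- sum(bad_eaf)
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
    report["n_kept"] <- nrow(out)
  }

  structure(out,
            trait_name = trait_name,
            trait_type = trait_type,
            validation = as.list(report),
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s (%s): %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Trait metadata accessors
#' @param x a `gwas_table`
#' @return character scalar
#' @export
trait_name <- function(x) attr(x, "trait_name")

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type")

# rebuild a gwas_table from a row subset, keeping metadata, skipping revalidation
subset_gwas <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = attr(x, "trait_name"),
            trait_type = attr(x, "trait_type"),
            validation = attr(x, "validation"),
            class = c("gwas_table", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Accepts tab- or whitespace-delimited files with a header row, including
#' the GCTA-COJO ".ma" dialect (`SNP A1 A2 freq b se p N`); gzip files are
#' read transparently. Column names are matched case-insensitively against
#' common synonyms unless an explicit `column_map` is given.
#'
#' Rows failing validation (missing beta/se/p, non-ACGT or identical
#' alleles, non-positive SE, p outside (0,1], duplicated rsIDs) are dropped
#' and counted in the attached validation report.
#'
#' @param path file path.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param column_map optional named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, `ncase`, `ncontrol`) to column names in the
#'   file.
#' @param trait_name trait label; defaults to the file name stem.
#' @return A [gwas_table()] with a `validation` attribute.
#' @export
read_gwas_table <- function(path, trait_type = c("quantitative", "binary"),
                            column_map = NULL, trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_gwas_table: cannot read '", path, "'")
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (is.null(trait_name)) {
    trait_name <- sub("\\.(tsv|txt|ma|csv)(\\.gz)?$", "", basename(path))
  }

  synonyms <- list(
    snp_id = c("snp", "snp_id", "rsid", "rs_id", "markername", "id", "variant_id"),
    chrom = c("chr", "chrom", "chromosome"),
    pos = c("pos", "bp", "position", "base_pair_location"),
    effect_allele = c("a1", "effect_allele", "ea", "allele1", "alt"),
    other_allele = c("a2", "other_allele", "oa", "nea", "allele2", "ref", "allele0"),
    eaf = c("freq", "frq", "eaf", "af", "effect_allele_frequency", "freq1"),
    beta = c("b", "beta", "effect", "effect_size"),
    se = c("se", "stderr", "standard_error", "sebeta"),
    pval = c("p", "pval", "p_value", "pvalue", "p_bolt_lmm"),
    n = c("n", "sample_size", "neff"),
    ncase = c("ncase", "n_case", "n_cases", "ncas"),
    ncontrol = c("ncontrol", "n_control", "n_controls", "ncon")
  )
  lc <- tolower(names(raw))
  pick <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      j <- match(tolower(column_map[[field]]), lc)
      if (is.na(j)) stop("read_gwas_table: mapped column '", column_map[[field]],
                         "' not found for field '", field, "'")
      return(j)
    }
    j <- match(synonyms[[field]], lc)
    j <- j[!is.na(j)]
    if (length(j) > 0) j[1] else NA_integer_
  }
  cols <- vapply(names(synonyms), pick, integer(1))
  for (field in c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")) {
    if (is.na(cols[[field]])) {
      stop("read_gwas_table: could not locate a column for '", field, "'")
    }
  }
  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(cols)) {
    if (!is.na(cols[[field]])) rec[[field]] <- raw[[cols[[field]]]]
  }
  tab <- gwas_table(rec, trait_name = trait_name, trait_type = trait_type)
  if (nrow(tab) == 0) {
    stop("read_gwas_table: no valid rows in '", path, "'")
  }
  tab
}

#' Write a GWAS table as canonical TSV
#'
#' Fixed column order `snp_id chrom pos effect_allele other_allele eaf beta
#' se pval n ncase ncontrol`.
#'
#' @param x a `gwas_table`
#' @param path output path (`.gz` suffix compresses).
#' @param report_path optional path for the JSON validation report.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path, report_path = NULL) {
  stopifnot(inherits(x, "gwas_table"))
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(report_path)) {
    rep <- c(list(trait_name = trait_name(x), trait_type = trait_type(x)),
             attr(x, "validation"))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
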