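#' Construct an LD matrix of squared correlations
#'
#' @param snp_ids character vector of rsIDs.
#' @param r2 square symmetric matrix of squared correlations, unit diagonal,
#'   values in \[0, 1\].
#' @return An `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids)) {
    stop("ld_matrix: dimension mismatch between snp_ids and r2")
  }
  if (anyNA(r2) || any(r2 < -1e-12) || any(r2 > 1 + 1e-12)) {
    stop("ld_matrix: r2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_matrix: r2 must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("ld_matrix: diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Two dialects: `"square"` (header row and first column of rsIDs, cells =
#' r2) and `"long"` (columns `snp_a`, `snp_b`, `r2`; unlisted pairs are
#' taken as r2 = 0). `"auto"` picks long format when the header has exactly
#' three columns named that way.
#'
#' @param path file path.
#' @param format `"auto"`, `"square"` or `"long"`.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  if (format == "auto") {
    format <- if (ncol(raw) == 3 &&
                  all(tolower(names(raw)) == c("snp_a", "snp_b", "r2"))) {
      "long"
    } else {
      "square"
    }
  }
  if (format == "long") {
    ids <- sort(unique(c(raw[[1]], raw[[2]])))
    r2 <- diag(length(ids))
    ia <- match(raw[[1]], ids)
    ib <- match(raw[[2]], ids)
    r2[cbind(ia, ib)] <- raw[[3]]
    r2[cbind(ib, ia)] <- raw[[3]]
    ld_matrix(ids, r2)
  } else {
    ids <- as.character(raw[[1]])
    ld_matrix(ids, as.matrix(raw[, -1, drop = FALSE]))
  }
}

new_prune_log <- function(snp_id = character(), reason = character(),
                          statistic = numeric(), rounds = 0L) {
  structure(data.frame(snp_id = snp_id, reason = reason,
                       statistic = statistic, stringsAsFactors = FALSE),
            rounds = rounds, class = c("prune_log", "data.frame"))
}

#' Write a prune log as TSV
#' @param log a `prune_log`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_prune_log <- function(log, path) {
  data.table::fwrite(as.data.frame(log), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter SNPs for genome-wide significance
#'
#' Retains records with `pval` strictly below the threshold.
#'
#' @param table a `gwas_table`.
#' @param p_threshold significance threshold (default `5e-8`).
#' @return A `gwas_table` (possibly empty).
#' @export
select_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "gwas_table"))
  if (nrow(table) == 0) stop("select_significant: empty table")
  subset_gwas(table, table$pval < p_threshold)
}

#' Greedy LD clumping of a GWAS table
#'
#' Sorts SNPs by ascending p-value (ties broken lexicographically by rsID),
#' then repeatedly accepts the best remaining SNP and discards every
#' remaining SNP with squared correlation at or above `r2_threshold` to any
#' accepted SNP. The returned set is pairwise independent at the threshold.
#' SNPs absent from the LD matrix are dropped conservatively (logged as
#' `absent_from_ld`). `ld = NULL` declares all SNPs mutually independent
#' (used with simulated unlinked variants).
#'
#' @param table a `gwas_table`.
#' @param ld an [ld_matrix()] covering the SNP universe, or `NULL`.
#' @param r2_threshold clumping threshold on r-squared (default 0.001).
#' @return `list(table = gwas_table, log = prune_log)`.
#' @export
ld_clump <- function(table, ld = NULL, r2_threshold = 0.001) {
  stopifnot(inherits(table, "gwas_table"))
  if (is.null(ld)) {
    return(list(table = table, log = new_prune_log(rounds = 0L)))
  }
  if (!inherits(ld, "ld_matrix")) stop("ld_clump: ld must be an ld_matrix or NULL")

  present <- table$snp_id %in% ld$snp_ids
  log_id <- table$snp_id[!present]
  log_reason <- rep("absent_from_ld", sum(!present))
  log_stat <- rep(NA_real_, sum(!present))
  tab <- subset_gwas(table, present)

  ord <- order(tab$pval, tab$snp_id)
  ids <- tab$snp_id[ord]
  r2 <- ld$r2[ids, ids, drop = FALSE]
  n <- length(ids)
  alive <- rep(TRUE, n)
  accepted <- logical(n)
  rounds <- 0L
  for (i in seq_len(n)) {
    if (!alive[i]) next
    rounds <- rounds + 1L
    accepted[i] <- TRUE
    clash <- alive & r2[i, ] >= r2_threshold
    clash[i] <- FALSE
    if (any(clash)) {
      log_id <- c(log_id, ids[clash])
      log_reason <- c(log_reason, rep(paste0("ld_with_", ids[i]), sum(clash)))
      log_stat <- c(log_stat, r2[i, clash])
      alive[clash] <- FALSE
    }
  }
  keep_ids <- ids[accepted]
  list(table = subset_gwas(tab, tab$snp_id %in% keep_ids),
       log = new_prune_log(log_id, log_reason, log_stat, rounds))
}

#' Remove instruments associated with other traits
#'
#' Cross-trait pruning in the style of lipid-MR sensitivity analyses:
#' drops any instrument of the target trait whose p-value in any other
#' trait's table falls below `p_threshold`. SNPs missing from an other
#' table are treated as not associated.
#'
#' @param target a `gwas_table` of instruments.
#' @param others list of `gwas_table`s for the competing traits.
#' @param p_threshold association threshold (default `1e-3`).
#' @return `list(table = gwas_table, log = prune_log)`.
#' @export
cross_trait_prune <- function(target, others, p_threshold = 1e-3) {
  stopifnot(inherits(target, "gwas_table"))
  if (inherits(others, "gwas_table")) others <- list(others)
  hit <- rep(FALSE, nrow(target))
  why <- rep(NA_character_, nrow(target))
  stat <- rep(NA_real_, nrow(target))
  for (o in others) {
    j <- match(target$snp_id, o$snp_id)
    p <- o$pval[j]
    new_hit <- !is.na(p) & p < p_threshold & !hit
    hit[new_hit] <- TRUE
    why[new_hit] <- paste0("associated_with_", trait_name(o))
    stat[new_hit] <- p[new_hit]
  }
  list(table = subset_gwas(target, !hit),
       log = new_prune_log(target$snp_id[hit], why[hit], stat[hit],
                           rounds = 1L))
}

# IVW fixed-effects kernel on ratio estimates: returns beta, Q, per-SNP Q
# contributions
ivw_kernel <- function(r, w) {
  beta <- sum(w * r) / sum(w)
  contrib <- w * (r - beta)^2
  list(beta = beta, Q = sum(contrib), contrib = contrib)
}

#' Heterogeneity-driven instrument pruning
#'
#' Iteratively removes the instrument with the largest contribution to
#' Cochran's Q, `w_j (r_j - beta)^2`, recomputing the IVW estimate each
#' round, until the Q p-value reaches `q_alpha` or only `min_k` instruments
#' remain. Deterministic; every removal is logged with its Q contribution.
#'
#' @param h single-exposure `harmonized_set` with at least `min_k`
#'   instruments.
#' @param q_alpha stopping threshold on the Q p-value (default 0.05).
#' @param min_k minimum instruments to retain (default 3).
#' @return `list(set = harmonized_set, log = prune_log)`.
#' @export
heterogeneity_prune <- function(h, q_alpha = 0.05, min_k = 3) {
  h <- single_exposure(h, "heterogeneity_prune")
  if (n_instruments(h) < min_k) {
    stop("heterogeneity_prune: fewer than min_k = ", min_k, " instruments")
  }
  log_id <- character()
  log_stat <- numeric()
  rounds <- 0L
  repeat {
    re <- ratio_estimates(h)
    k <- nrow(re)
    fit <- ivw_kernel(re$r, re$w)
    p <- stats::pchisq(fit$Q, df = k - 1, lower.tail = FALSE)
    if (p >= q_alpha || k <= min_k) break
    drop <- which.max(fit$contrib)
    log_id <- c(log_id, re$snp_id[drop])
    log_stat <- c(log_stat, fit$contrib[drop])
    h <- subset_harmonized(h, -drop)
    rounds <- rounds + 1L
  }
  list(set = h,
       log = new_prune_log(log_id, rep("q_contribution", length(log_id)),
                           log_stat, rounds))
}
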