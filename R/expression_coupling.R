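## circRNA-host expression coupling: normalization, correlation profiling,
## a self-contained exact differential-expression test, and
## reversed/coordinated pattern classification.

#' Normalize a count matrix to RPM or RPKM
#'
#' RPM = count * 1e6 / library size; RPKM additionally divides by feature
#' length in kb.
#'
#' @param mat Features x samples matrix of non-negative counts.
#' @param mode `"RPM"` or `"RPKM"`.
#' @param lengths Feature lengths in nt (required for RPKM), in row order
#'   or named by rownames.
#' @param lib_sizes Library sizes; default column sums.
#' @return Normalized matrix of the same shape.
#' @export
normalize_counts <- function(mat, mode = c("RPM", "RPKM"), lengths = NULL,
                             lib_sizes = NULL) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (is.null(lib_sizes)) lib_sizes <- colSums(mat)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  rpm <- sweep(mat, 2, lib_sizes, "/") * 1e6
  if (mode == "RPM") return(rpm)
  if (is.null(lengths)) stop("RPKM requires feature lengths")
  if (!is.null(names(lengths)) && !is.null(rownames(mat))) {
    lengths <- lengths[rownames(mat)]
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("invalid feature lengths")
  sweep(rpm, 1, lengths / 1e3, "/")
}

#' Pearson correlation with the package's degeneracy convention
#'
#' Standard product-moment correlation; undefined (NA, not 0) when either
#' vector has zero variance or fewer than three observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1,1]`, or NA.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' circRNA-host expression correlation profile
#'
#' One Pearson correlation per circRNA-host pair, computed across samples
#' on log2(RPM + 1) by default (an `"rpm"` mode correlates raw RPM).
#' Pairs whose host is absent from the gene matrix are skipped with a
#' warning.
#'
#' @param circ_mat circRNA count matrix (features x samples).
#' @param gene_mat Gene count matrix with matching sample columns.
#' @param host_map data.frame: `circ_id`, `gene_id`.
#' @param method `"log2rpm"` (default) or `"rpm"`.
#' @return List: `records` (data.frame circ_id, host_gene_id, pearson_r),
#'   `median_r` (over non-NA records).
#' @export
coupling_profile <- function(circ_mat, gene_mat, host_map,
                             method = c("log2rpm", "rpm")) {
  method <- match.arg(method)
  circ_rpm <- normalize_counts(circ_mat, "RPM")
  gene_rpm <- normalize_counts(gene_mat, "RPM")
  if (method == "log2rpm") {
    circ_rpm <- log2(circ_rpm + 1)
    gene_rpm <- log2(gene_rpm + 1)
  }
  keep <- host_map$circ_id %in% rownames(circ_mat)
  missing_host <- keep & !(host_map$gene_id %in% rownames(gene_mat))
  if (any(missing_host)) {
    warning(sum(missing_host), " pair(s) skipped: host absent from gene matrix")
  }
  hm <- host_map[keep & !missing_host, , drop = FALSE]
  r <- vapply(seq_len(nrow(hm)), function(i) {
    pearson_r(circ_rpm[hm$circ_id[i], ], gene_rpm[hm$gene_id[i], ])
  }, numeric(1))
  records <- data.frame(circ_id = hm$circ_id, host_gene_id = hm$gene_id,
                        pearson_r = r, stringsAsFactors = FALSE)
  list(records = records, median_r = stats::median(r, na.rm = TRUE))
}

# Two-sided exact binomial p-value (minlike convention: sum of point
# probabilities not exceeding that of the observation, with 1e-7 relative
# slack), vectorized over observations.
binom_p_twosided <- function(x, n, p0) {
  vapply(seq_along(x), function(i) {
    if (n[i] == 0) return(1)
    d <- stats::dbinom(0:n[i], n[i], p0)
    sum(d[d <= d[x[i] + 1] * (1 + 1e-7)])
  }, numeric(1))
}

#' Exact conditional differential-expression test
#'
#' Self-contained dispersion-free test: for each feature, pooled counts of
#' the two groups are compared with an exact two-sided binomial test of the
#' treatment fraction against the library-size-proportional expectation.
#' log2 fold changes are computed on group-mean RPM with a pseudocount;
#' q-values by Benjamini-Hochberg. A feature is called up/down iff
#' q < alpha and |log2fc| >= fc_floor. Anti-conservative under biological
#' overdispersion; `dispersion` > 1 divides the pooled counts to inflate
#' the variance allowance.
#'
#' @param mat Features x samples count matrix.
#' @param treat_cols,control_cols Column indices or names of the two groups.
#' @param alpha Significance level on q (default 0.05).
#' @param fc_floor Minimum |log2fc| (default 1).
#' @param pseudocount Pseudocount in RPM units (default 1).
#' @param dispersion Count deflation factor >= 1 (default 1 = pure
#'   Poisson).
#' @return data.frame: `feature`, `log2fc`, `p`, `q`, `state`
#'   (up/down/ns).
#' @export
de_test <- function(mat, treat_cols, control_cols, alpha = 0.05,
                    fc_floor = 1, pseudocount = 1, dispersion = 1) {
  mat <- as.matrix(mat)
  tm <- mat[, treat_cols, drop = FALSE]
  cm <- mat[, control_cols, drop = FALSE]
  if (ncol(tm) < 1 || ncol(cm) < 1) stop("each group needs >= 1 sample")
  lib_t <- sum(tm); lib_c <- sum(cm)
  if (lib_t <= 0 || lib_c <= 0) stop("library sizes must be > 0")
  xt <- rowSums(tm); xc <- rowSums(cm)
  rpm_t <- xt / lib_t * 1e6
  rpm_c <- xc / lib_c * 1e6
  log2fc <- log2((rpm_t + pseudocount) / (rpm_c + pseudocount))
  xs <- round(xt / dispersion)
  ns <- round((xt + xc) / dispersion)
  p0 <- lib_t / (lib_t + lib_c)
  p <- binom_p_twosided(xs, ns, p0)
  q <- stats::p.adjust(p, method = "BH")
  state <- ifelse(q < alpha & abs(log2fc) >= fc_floor,
                  ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             log2fc = log2fc, p = p, q = q, state = state,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential expression for every stress-vs-control contrast
#'
#' @param mat Features x samples count matrix.
#' @param samples data.frame: `sample_id`, `condition` matching the matrix
#'   columns (by `sample_id` = colnames).
#' @param control Control condition label (default "CK").
#' @param ... Passed to [de_test()].
#' @return Named list of [de_test()] results, one per stress condition.
#' @export
de_all_contrasts <- function(mat, samples, control = "CK", ...) {
  conds <- setdiff(unique(samples$condition), control)
  ctrl_cols <- samples$sample_id[samples$condition == control]
  stats::setNames(lapply(conds, function(cc) {
    de_test(mat, samples$sample_id[samples$condition == cc], ctrl_cols, ...)
  }), conds)
}

#' Classify the circRNA/host differential-expression pattern
#'
#' Reversed = opposite DE directions; Coordinated = same direction;
#' HostStable = circ DE while the host is stable; CircStable = host DE
#' while the circ is stable; NS = neither DE. Total and deterministic over
#' states in \{up, down, ns\}.
#'
#' @param circ_state,host_state Character vectors of DE states.
#' @return Character vector of patterns.
#' @export
classify_pattern <- function(circ_state, host_state) {
  stopifnot(all(circ_state %in% c("up", "down", "ns")),
            all(host_state %in% c("up", "down", "ns")))
  mapply(function(cs, hs) {
    if (cs != "ns" && hs != "ns") {
      if (cs == hs) "Coordinated" else "Reversed"
    } else if (cs != "ns") "HostStable"
    else if (hs != "ns") "CircStable"
    else "NS"
  }, circ_state, host_state, USE.NAMES = FALSE)
}

#' Full circRNA-host coupling analysis
#'
#' Correlation profile plus per-condition fold changes, DE states, and
#' pattern calls for every circRNA-host pair.
#'
#' @param circ_mat,gene_mat Count matrices with identical sample columns.
#' @param host_map data.frame `circ_id`, `gene_id`.
#' @param samples data.frame `sample_id`, `condition`.
#' @param control Control condition (default "CK").
#' @param method Correlation scale (see [coupling_profile()]).
#' @param ... Passed to [de_test()].
#' @return List: `coupling` (per-pair correlation records), `median_r`,
#'   `de_circ`, `de_gene` (per-condition DE tables), `patterns`
#'   (long data.frame: circ_id, host_gene_id, condition, circ_state,
#'   host_state, circ_log2fc, host_log2fc, pattern).
#' @export
coupling_analysis <- function(circ_mat, gene_mat, host_map, samples,
                              control = "CK", method = "log2rpm", ...) {
  prof <- coupling_profile(circ_mat, gene_mat, host_map, method = method)
  de_c <- de_all_contrasts(circ_mat, samples, control, ...)
  de_g <- de_all_contrasts(gene_mat, samples, control, ...)
  pats <- do.call(rbind, lapply(names(de_c), function(cc) {
    dc <- de_c[[cc]]; dg <- de_g[[cc]]
    hm <- prof$records
    ic <- match(hm$circ_id, dc$feature)
    ig <- match(hm$host_gene_id, dg$feature)
    data.frame(circ_id = hm$circ_id, host_gene_id = hm$host_gene_id,
               condition = cc,
               circ_state = dc$state[ic], host_state = dg$state[ig],
               circ_log2fc = dc$log2fc[ic], host_log2fc = dg$log2fc[ig],
               pattern = classify_pattern(dc$state[ic], dg$state[ig]),
               stringsAsFactors = FALSE)
  }))
  rownames(pats) <- NULL
  list(coupling = prof$records, median_r = prof$median_r,
       de_circ = de_c, de_gene = de_g, patterns = pats)
}
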