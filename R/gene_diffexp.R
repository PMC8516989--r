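# Postnatal-vs-prenatal differential expression screen: log2 scaling,
# group-mean fold change, per-gene significance, joint fold-change +
# Bonferroni selection and enrichment-ready export.

EXPR_GROUPS <- c("target_postnatal", "control_prenatal")

#' Expression matrix with a scale flag
#'
#' Genes in rows (unique symbols), samples in columns. Linear-scale values
#' are RPKM (reads per kilobase per million mapped reads) and must be
#' non-negative; the log2 scale is obtained with [to_log2()].
#'
#' @param values Numeric matrix with row names (gene symbols) and column
#'   names (sample IDs).
#' @param scale `"linear"` or `"log2"`.
#' @return An `expression_matrix` (matrix with a `scale` attribute).
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene symbols (rownames) and sample IDs (colnames) are required",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale (RPKM) values must be non-negative", call. = FALSE)
  }
  structure(values, scale = scale, class = c("expression_matrix", "matrix",
                                             "array"))
}

expr_scale <- function(mat) attr(mat, "scale")

#' Log2-transform an expression matrix
#'
#' `value -> log2(value + pseudocount)`. Applying it twice is refused.
#'
#' @param mat A linear-scale [expression_matrix()].
#' @param pseudocount Offset added before the log (default 1, so RPKM 0
#'   maps to 0 and RPKM 1 to 1).
#' @return A log2-scale `expression_matrix`.
#' @export
to_log2 <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (expr_scale(mat) == "log2") {
    stop("matrix is already log2-scaled", call. = FALSE)
  }
  stopifnot(pseudocount >= 0)
  expression_matrix(log2(unclass(mat) + pseudocount), scale = "log2")
}

check_metadata <- function(mat, metadata) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  bad <- setdiff(unique(metadata$group), EXPR_GROUPS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing_cols)) {
    stop("metadata lacks sample(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  groups <- metadata$group[match(colnames(mat), metadata$sample_id)]
  for (g in EXPR_GROUPS) {
    if (sum(groups == g) < 2L) {
      stop("group '", g, "' needs at least 2 samples", call. = FALSE)
    }
  }
  groups
}

#' Per-gene log2 fold change between groups
#'
#' The fold change of each gene is the mean log2 expression over target
#' (postnatal) samples minus the mean over control (prenatal) samples; the
#' linear fold is `2^log2_fc`.
#'
#' @param mat A log2-scale [expression_matrix()].
#' @param metadata Data.frame with `sample_id` and `group`
#'   (`target_postnatal` / `control_prenatal`) covering every column.
#' @return Named numeric vector of log2 fold changes.
#' @export
fold_change <- function(mat, metadata) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (expr_scale(mat) != "log2") {
    stop("fold_change() expects a log2-scale matrix; call to_log2() first",
         call. = FALSE)
  }
  groups <- check_metadata(mat, metadata)
  tgt <- rowMeans(mat[, groups == "target_postnatal", drop = FALSE])
  ctl <- rowMeans(mat[, groups == "control_prenatal", drop = FALSE])
  tgt - ctl
}

#' Per-gene two-sample significance test
#'
#' Two-sided two-sample t-test of target vs control log2 expression, gene
#' by gene. The default pools the within-group variances (Student's test,
#' df `n1 + n2 - 2`), which is the standard choice for expression screens
#' with a handful of samples per group and a shared noise model;
#' `welch = TRUE` switches to Welch's unequal-variance test. Degenerate
#' genes with zero variance in both groups get `p = 1` when the group
#' means are equal and `p = 0` (flagged) when they differ.
#'
#' @inheritParams fold_change
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return Named numeric vector of p-values with a logical attribute
#'   `degenerate` marking zero-variance genes.
#' @export
per_gene_test <- function(mat, metadata, welch = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (expr_scale(mat) != "log2") {
    stop("per_gene_test() expects a log2-scale matrix", call. = FALSE)
  }
  groups <- check_metadata(mat, metadata)
  tgt <- unclass(mat)[, groups == "target_postnatal", drop = FALSE]
  ctl <- unclass(mat)[, groups == "control_prenatal", drop = FALSE]
  n <- nrow(mat)
  p <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    x <- tgt[i, ]; y <- ctl[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      degen[i] <- TRUE
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y, var.equal = !welch)$p.value
    }
  }
  names(p) <- rownames(mat)
  attr(p, "degenerate") <- degen
  p
}

#' Full differential expression screen
#'
#' Runs [fold_change()] and [per_gene_test()] and assembles the per-gene
#' result table with selection flags and descending-fold ranks.
#'
#' @param mat An [expression_matrix()]; linear-scale input is log2-scaled
#'   first with `pseudocount`.
#' @param metadata Sample metadata (see [fold_change()]).
#' @param fc_threshold Linear fold-change threshold; a gene passes when
#'   `2^log2_fc > fc_threshold` (set `linear_fc = FALSE` to threshold the
#'   log2 value instead).
#' @param alpha Significance threshold applied directly to the per-gene
#'   p-value (the Bonferroni-corrected level); `NULL` uses `0.05 / n_genes`.
#' @param pseudocount Offset for the log2 transform of linear input.
#' @param direction `"up"` keeps postnatal-upregulated genes only (the
#'   default); `"both"` thresholds `|fold|`.
#' @param linear_fc Interpret `fc_threshold` on the linear fold scale
#'   (default) rather than in log2 units.
#' @param welch Passed to [per_gene_test()].
#' @return A `diff_expr_result` data.frame: `gene`, `log2_fc`,
#'   `fold_linear`, `p`, `p_bonferroni`, `passes_fc`, `passes_p`,
#'   `selected`, `rank` (1 = largest fold change among selected ordering).
#' @export
diff_expression <- function(mat, metadata, fc_threshold = 4,
                            alpha = 5.7e-6, pseudocount = 1,
                            direction = c("up", "both"),
                            linear_fc = TRUE, welch = FALSE) {
  direction <- match.arg(direction)
  if (expr_scale(mat) == "linear") mat <- to_log2(mat, pseudocount)
  lfc <- fold_change(mat, metadata)
  p <- per_gene_test(mat, metadata, welch = welch)
  n <- length(lfc)
  if (is.null(alpha)) alpha <- 0.05 / n
  log2_threshold <- if (linear_fc) log2(fc_threshold) else fc_threshold
  effective_lfc <- if (direction == "both") abs(lfc) else lfc
  res <- data.frame(
    gene = names(lfc), log2_fc = unname(lfc),
    fold_linear = 2^unname(lfc),
    p = unname(p), p_bonferroni = pmin(1, unname(p) * n),
    passes_fc = unname(effective_lfc > log2_threshold),
    passes_p = unname(p < alpha),
    stringsAsFactors = FALSE
  )
  res$selected <- res$passes_fc & res$passes_p
  ord <- order(-effective_lfc, res$p, res$gene)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_len(n)
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "alpha") <- alpha
  attr(res, "direction") <- direction
  class(res) <- c("diff_expr_result", "data.frame")
  res
}

#' Select and rank the differentially expressed genes
#'
#' Genes passing both the fold-change and significance thresholds, ranked
#' by descending log2 fold change (ties broken by ascending p, then gene
#' symbol).
#'
#' @param result A `diff_expr_result` from [diff_expression()].
#' @return The selected subset, ranked; a `diff_expr_result` data.frame.
#' @export
select_genes <- function(result) {
  stopifnot(inherits(result, "diff_expr_result"))
  sel <- result[result$selected, , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Export a ranked gene list for external enrichment analysis
#'
#' Writes a one-symbol-per-line text file (the format enrichment web
#' services ingest) plus a companion TSV with `gene`, `log2_fc` and `p`.
#'
#' @param selection A ranked `diff_expr_result` (typically from
#'   [select_genes()]).
#' @param path Output path for the symbol list; the TSV lands next to it
#'   with a `.tsv` extension appended.
#' @return Invisibly, the paths written.
#' @export
export_gene_list <- function(selection, path) {
  stopifnot(is.data.frame(selection),
            all(c("gene", "log2_fc", "p") %in% names(selection)))
  if (!nrow(selection)) {
    warning("empty gene selection; writing empty files", call. = FALSE)
  }
  writeLines(selection$gene, path)
  tsv_path <- paste0(path, ".tsv")
  out <- selection[, c("gene", "log2_fc", "p")]
  out$log2_fc <- sprintf("%.17g", out$log2_fc)
  out$p <- sprintf("%.17g", out$p)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(path, tsv_path))
}
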