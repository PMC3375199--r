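#' Build an expression matrix object
#'
#' @param values Numeric matrix, probes x samples (rownames = probe ids,
#'   colnames = sample ids), no missing values.
#' @param groups Named character vector mapping sample_id to condition label
#'   (names must cover all columns of `values`).
#' @return List of class `"g4prom_expr"` with elements `values` and `groups`
#'   (reordered to the column order of `values`).
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("expression matrix needs probe rownames and sample colnames")
  if (!all(colnames(values) %in% names(groups)))
    stop("groups must label every sample column")
  groups <- groups[colnames(values)]
  if (length(unique(groups)) < 2L)
    stop("need at least 2 conditions")
  if (any(table(groups) < 2L))
    stop("each condition needs at least 2 replicates")
  structure(list(values = values, groups = groups), class = "g4prom_expr")
}

#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix TSV has probe ids in the first column and sample ids in the
#' header; the sample sheet has columns `sample_id` and `condition`.
#'
#' @param matrix_path,samples_path Paths to the two TSV files.
#' @return A `"g4prom_expr"` object.
#' @export
read_expression <- function(matrix_path, samples_path) {
  m <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  vals <- as.matrix(m[, -1L, drop = FALSE])
  rownames(vals) <- as.character(m[[1L]])
  ss <- .read_tsv(samples_path)
  expression_matrix(vals, stats::setNames(ss$condition, ss$sample_id))
}

#' Quantile normalization
#'
#' Classic algorithm: each column's rank-i value is replaced by the mean of
#' all columns' i-th order statistics; ties within a column receive the mean
#' of their candidate values.  Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param expr A `"g4prom_expr"` object (or bare numeric matrix).
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(expr) {
  if (inherits(expr, "g4prom_expr")) {
    expr$values <- limma::normalizeQuantiles(expr$values, ties = TRUE)
    expr
  } else {
    limma::normalizeQuantiles(as.matrix(expr), ties = TRUE)
  }
}

#' Per-probe one-way ANOVA p-values
#'
#' Vectorized fixed-effects one-way ANOVA across condition groups; the
#' p-value comes from the F distribution with (g-1, n-g) degrees of freedom.
#' Probes with zero between-group and zero within-group variance get p = 1 by
#' convention (counted in a message).
#'
#' @param expr A `"g4prom_expr"` object.
#' @return Numeric vector of p-values, named by probe.
#' @export
anova_per_probe <- function(expr) {
  stopifnot(inherits(expr, "g4prom_expr"))
  v <- expr$values
  g <- factor(expr$groups)
  ng <- nlevels(g)
  n <- ncol(v)
  stopifnot(ng >= 2L, all(table(g) >= 2L))
  # group means via indicator algebra
  gm <- vapply(levels(g), function(l) rowMeans(v[, g == l, drop = FALSE]),
               numeric(nrow(v)))
  sizes <- as.integer(table(g)[levels(g)])
  grand <- rowMeans(v)
  ssb <- as.numeric(gm^2 %*% sizes) - n * grand^2
  sst <- rowSums(v^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  f <- (ssb / (ng - 1L)) / (ssw / (n - ng))
  p <- stats::pf(f, ng - 1L, n - ng, lower.tail = FALSE)
  flat <- ssw < 1e-24 & ssb < 1e-24
  if (any(flat)) {
    p[flat] <- 1
    message(sum(flat), " probe(s) with zero variance; p set to 1")
  }
  # zero within-group but nonzero between-group variance: F infinite, p = 0
  p[ssw < 1e-24 & !flat] <- 0
  stats::setNames(p, rownames(v))
}

#' Correlation of each probe to a condition indicator profile
#'
#' Pearson correlation between each probe's per-sample values and the 0/1
#' indicator of the given condition ("up with condition"); the correlation to
#' the negated indicator ("down with condition") is its negative.
#' Zero-variance probes get `NA` and are excluded from selection (counted in
#' a message).
#'
#' @param expr A `"g4prom_expr"` object.
#' @param condition A condition label present in `expr$groups`.
#' @return Numeric vector of correlations in `[-1, 1]`, named by probe.
#' @export
profile_correlation <- function(expr, condition) {
  stopifnot(inherits(expr, "g4prom_expr"))
  if (!condition %in% expr$groups)
    stop("condition not present: ", condition)
  ind <- as.numeric(expr$groups == condition)
  sds <- apply(expr$values, 1L, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(t(expr$values), ind)))
  r[sds == 0] <- NA_real_
  if (anyNA(r))
    message(sum(is.na(r)), " zero-variance probe(s) excluded from selection")
  stats::setNames(r, rownames(expr$values))
}

#' Select up-, down- and unchanged gene sets
#'
#' A probe is `up` if its ANOVA p <= `p_max` and its correlation to the
#' condition indicator is >= `r_min`; `down` if p <= `p_max` and the
#' correlation to the negated indicator (`r_down = -r_up` for an indicator
#' profile) is >= `r_min`; `unchanged` if p > `p_unchanged`.  Probe sets are
#' mapped to gene sets through `probe_gene` (many-to-many allowed; genes
#' deduplicated).  A Benjamini-Hochberg adjusted p is emitted alongside but
#' plays no role in selection.
#'
#' @param anova_p Named numeric vector from [anova_per_probe()].
#' @param r_up Named numeric vector from [profile_correlation()].
#' @param r_down Correlations to the negated indicator (default `-r_up`).
#' @param p_max,r_min,p_unchanged Selection thresholds (defaults 0.05, 0.9,
#'   0.75).
#' @param probe_gene Data.frame with columns `probe_id`, `gene_id`; default
#'   maps each probe to itself.
#' @return List of class `"g4prom_de"` with `stats` (per-probe data.frame:
#'   `probe_id`, `anova_p`, `q`, `r_up`, `r_down`, `call`), gene sets `up`,
#'   `down`, `unchanged`, `universe`, and the thresholds used.
#' @export
select_sets <- function(anova_p, r_up, r_down = -r_up, p_max = 0.05,
                        r_min = 0.9, p_unchanged = 0.75,
                        probe_gene = NULL) {
  stopifnot(length(anova_p) == length(r_up),
            length(r_up) == length(r_down))
  probes <- names(anova_p)
  if (is.null(probe_gene))
    probe_gene <- data.frame(probe_id = probes, gene_id = probes,
                             stringsAsFactors = FALSE)
  usable <- !is.na(r_up) & !is.na(r_down)
  up <- usable & anova_p <= p_max & r_up >= r_min
  down <- usable & anova_p <= p_max & r_down >= r_min
  stopifnot("a probe cannot be both up and down" = !any(up & down))
  unchanged <- anova_p > p_unchanged
  to_genes <- function(sel) {
    unique(probe_gene$gene_id[probe_gene$probe_id %in% probes[sel]])
  }
  call <- ifelse(up, "up", ifelse(down, "down",
                 ifelse(unchanged, "unchanged", "none")))
  structure(list(
    stats = data.frame(probe_id = probes, anova_p = as.numeric(anova_p),
                       q = stats::p.adjust(anova_p, "BH"),
                       r_up = as.numeric(r_up), r_down = as.numeric(r_down),
                       call = call, stringsAsFactors = FALSE),
    up = to_genes(up), down = to_genes(down), unchanged = to_genes(unchanged),
    universe = unique(probe_gene$gene_id),
    thresholds = list(p_max = p_max, r_min = r_min,
                      p_unchanged = p_unchanged)),
    class = "g4prom_de")
}

#' Intersect differential-expression selections across controls
#'
#' When several control conditions are compared against the same condition of
#' interest, a gene is retained only if selected against every control;
#' unchanged sets are intersected likewise.
#'
#' @param ... Two or more `"g4prom_de"` objects.
#' @return List with intersected `up`, `down`, `unchanged` and the common
#'   `universe`.
#' @export
intersect_selections <- function(...) {
  sels <- list(...)
  stopifnot(length(sels) >= 2L)
  pick <- function(field) Reduce(intersect, lapply(sels, `[[`, field))
  list(up = pick("up"), down = pick("down"), unchanged = pick("unchanged"),
       universe = pick("universe"))
}

#' Run the full expression-selection stage
#'
#' Quantile normalization, per-probe ANOVA, indicator correlation to the
#' condition of interest, and thresholded selection.
#'
#' @param expr A `"g4prom_expr"` object.
#' @param condition Condition of interest.
#' @inheritParams select_sets
#' @return A `"g4prom_de"` object.
#' @export
run_de <- function(expr, condition, p_max = 0.05, r_min = 0.9,
                   p_unchanged = 0.75, probe_gene = NULL) {
  expr <- quantile_normalize(expr)
  p <- anova_per_probe(expr)
  r <- profile_correlation(expr, condition)
  select_sets(p, r, p_max = p_max, r_min = r_min,
              p_unchanged = p_unchanged, probe_gene = probe_gene)
}
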