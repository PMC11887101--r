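# Pearson and full-order partial correlation (Gaussian graphical model)
# networks over normalized metabolites, optional correction for mQTL
# genotypes, and interchange-format export.

#' Pearson correlation matrix of a metabolite table
#'
#' @param data Tibble (`sample_id` + numeric columns) or numeric matrix,
#'   no missing values.
#' @return Symmetric correlation matrix.
#' @export
pearson_matrix <- function(data) {
  m <- if (is.data.frame(data)) {
    as.matrix(data[setdiff(names(data), c("sample_id", "plate", "is_pool"))])
  } else as.matrix(data)
  if (anyNA(m)) abort("missing values not allowed")
  zv <- apply(m, 2, var) == 0
  if (any(zv)) {
    abort(paste0("zero-variance column(s): ", toString(colnames(m)[zv])))
  }
  cor(m)
}

#' Full-order partial correlation matrix by matrix inversion
#'
#' Inverts the correlation matrix R to the precision matrix Omega and scales:
#' `PCC_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`; the diagonal is set
#' to 1. Each entry is the correlation of metabolites i and j conditional on
#' all others. If R is near-singular (condition number > `cond_limit`) a
#' small ridge (`ridge` on the diagonal) is applied and the result flagged
#' via the `"ridged"` attribute; with `regularize = FALSE` such input is an
#' error.
#'
#' @param data Metabolite tibble/matrix (rows = samples) or an
#'   already-computed correlation matrix (square symmetric, unit diagonal).
#' @param regularize Allow the ridge fallback (default `TRUE`).
#' @param cond_limit,ridge Condition-number trigger and ridge size.
#' @return Symmetric PCC matrix with attribute `ridged`.
#' @export
partial_correlation_matrix <- function(data, regularize = TRUE,
                                       cond_limit = 1e10, ridge = 1e-4) {
  R <- if (is.matrix(data) && nrow(data) == ncol(data) &&
           isTRUE(all.equal(unname(diag(data)), rep(1, ncol(data))))) {
    data
  } else {
    pearson_matrix(data)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ridged <- FALSE
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit) {
    if (!regularize) abort("correlation matrix is singular or ill-conditioned")
    R <- R + diag(ridge, ncol(R))
    ridged <- TRUE
  }
  omega <- solve(R)
  s <- 1 / sqrt(diag(omega))
  pcc <- -omega * tcrossprod(s)
  diag(pcc) <- 1
  dimnames(pcc) <- dimnames(R)
  attr(pcc, "ridged") <- ridged
  pcc
}

#' Build a Gaussian graphical model from a PCC matrix
#'
#' Two metabolites are linked when their partial correlation exceeds the
#' threshold (strictly; by default the signed value, so only positive
#' conditional dependencies form edges — `mode = "absolute"` thresholds
#' |PCC|). Unconnected metabolites are kept as singletons.
#'
#' @param pcc PCC matrix from [partial_correlation_matrix()].
#' @param threshold Edge threshold (default 0.3, strict `>`).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param pearson Optional Pearson matrix stored alongside for reporting.
#' @return A `ggm` object: list with `nodes`, `edges` (tibble from, to,
#'   pcc), `singletons`, `threshold`, `mode`, `pcc`, `pearson`,
#'   `corrected` flag.
#' @export
build_ggm <- function(pcc, threshold = 0.3, mode = c("signed", "absolute"),
                      pearson = NULL) {
  mode <- match.arg(mode)
  if (!isSymmetric(unname(pcc), tol = 1e-8)) abort("PCC matrix must be symmetric")
  nodes <- colnames(pcc) %||% paste0("M", seq_len(ncol(pcc)))
  val <- if (mode == "absolute") abs(pcc) else pcc
  sel <- which(upper.tri(val) & val > threshold, arr.ind = TRUE)
  edges <- tibble(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                  pcc = pcc[sel])
  connected <- unique(c(edges$from, edges$to))
  structure(list(
    nodes = nodes, edges = edges,
    singletons = setdiff(nodes, connected),
    threshold = threshold, mode = mode,
    pcc = pcc, pearson = pearson,
    corrected = isTRUE(attr(pcc, "genotype_corrected"))
  ), class = "ggm")
}

#' @export
print.ggm <- function(x, ...) {
  cat("<ggm> ", length(x$nodes), " nodes: ",
      length(x$nodes) - length(x$singletons), " connected by ",
      nrow(x$edges), " edges (PCC > ", x$threshold, "), ",
      length(x$singletons), " singletons",
      if (x$corrected) ", genotype-corrected", "\n", sep = "")
  invisible(x)
}

#' Genotype-corrected correlation network
#'
#' Removes the genetic signal of identified mQTL before network estimation:
#' each metabolite is replaced by its least-squares residuals on the lead
#' SNPs coded as genotype-class dummy variables (two indicators per SNP:
#' heterozygote and minor-allele homozygote), then Pearson and partial
#' correlations are recomputed. Monomorphic lead SNPs are dropped with a
#' warning; with no usable SNP the uncorrected network is returned.
#'
#' @param normalized Normalized metabolite tibble
#'   ([normalize_metabolites()] output).
#' @param geno [genotype_matrix()] on the same samples.
#' @param lead_snps Character vector of mQTL lead SNP ids.
#' @param threshold,mode Passed to [build_ggm()].
#' @return A `ggm` object (with `corrected = TRUE` when any SNP was used).
#' @export
genotype_corrected_pcc <- function(normalized, geno, lead_snps,
                                   threshold = 0.3, mode = "signed") {
  ids <- setdiff(names(normalized), "sample_id")
  m <- as.matrix(normalized[ids])
  G <- dosage_matrix(geno)
  lead_snps <- intersect(lead_snps, colnames(G))
  cols <- list()
  for (s in lead_snps) {
    x <- G[, s]
    if (anyNA(x)) x[is.na(x)] <- round(mean(x, na.rm = TRUE))
    if (var(x) == 0) {
      warn(paste0("lead SNP ", s, " is monomorphic; dropped"))
      next
    }
    for (lev in setdiff(sort(unique(x)), min(x))) {
      cols[[paste0(s, "_", lev)]] <- as.numeric(x == lev)
    }
  }
  if (!length(cols)) {
    pcc <- partial_correlation_matrix(m)
    return(build_ggm(pcc, threshold = threshold, mode = mode,
                     pearson = pearson_matrix(m)))
  }
  D <- do.call(cbind, cols)
  X <- cbind(1, D)
  qr_x <- qr(X)
  resid <- qr.resid(qr_x, m)
  colnames(resid) <- ids
  pr <- pearson_matrix(resid)
  pcc <- partial_correlation_matrix(resid)
  attr(pcc, "genotype_corrected") <- TRUE
  build_ggm(pcc, threshold = threshold, mode = mode, pearson = pr)
}

#' Export a network to interchange formats
#'
#' `edge_tsv` writes the weighted edge list; `graphml` writes nodes
#' (singletons included) and edges with a `pcc` attribute; `sif` writes
#' Cytoscape simple-interaction lines (singletons cannot be represented and
#' are dropped with a warning).
#'
#' @param network A `ggm` object.
#' @param path Output file.
#' @param format `"edge_tsv"`, `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edge_tsv", "graphml", "sif")) {
  if (!inherits(network, "ggm")) abort("network must be a ggm object")
  format <- match.arg(format)
  e <- network$edges
  if (format == "edge_tsv") {
    readr::write_tsv(e, path, progress = FALSE)
  } else if (format == "graphml") {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE), fixed = TRUE)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="pcc" attr.type="double"/>',
      '  <graph id="ggm" edgedefault="undirected">',
      paste0('    <node id="', esc(network$nodes), '"/>'),
      if (nrow(e)) paste0('    <edge source="', esc(e$from), '" target="',
                          esc(e$to), '"><data key="w">', e$pcc, '</data></edge>'),
      "  </graph>", "</graphml>")
    readr::write_lines(lines, path)
  } else {
    if (length(network$singletons)) {
      warn("sif format cannot represent singleton nodes; they are omitted")
    }
    readr::write_lines(paste(e$from, "pcc", e$to), path)
  }
  invisible(path)
}
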