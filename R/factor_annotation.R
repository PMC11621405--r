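#' Associate transcriptome-wide genes with latent factors
#'
#' Correlates each gene of a cell-type-specific expression matrix (full
#' transcriptome, not just the shared panel) with each factor's cell
#' loadings, by Spearman correlation (default) or cosine similarity. This
#' extends the shared-gene factors to genome-wide gene modules for pathway
#' and ligand-receptor interpretation.
#'
#' @param E cells x genes expression matrix (a [count_matrix()] or plain
#'   matrix) restricted to one cell type.
#' @param H cells x LF loading matrix over the same cells in the same
#'   order.
#' @param method `"spearman"` or `"cosine"`.
#' @param cell_type optional label stored with the result.
#' @return A `FactorGeneAssociation`: list with `values` (genes x LF
#'   scores), `method`, `cell_type`, `constant_genes` (genes with zero
#'   variance, scored 0).
#' @export
associate_genes <- function(E, H, method = c("spearman", "cosine"),
                            cell_type = NA_character_) {
  method <- match.arg(method)
  E <- as.matrix(strip_cm(E)); H <- as.matrix(H)
  if (nrow(E) != nrow(H)) stop("E and H must cover the same cells")
  if (nrow(E) < 3) stop("need at least 3 cells")
  constant <- apply(E, 2, function(col) length(unique(col)) == 1)
  if (method == "spearman") {
    vals <- suppressWarnings(cor(E, H, method = "spearman"))
    vals[constant, ] <- 0
  } else {
    En <- sqrt(colSums(E^2)); Hn <- sqrt(colSums(H^2))
    vals <- crossprod(E, H) /
      (En %o% pmax(Hn, .Machine$double.eps))
    vals[En == 0, ] <- 0
  }
  vals[!is.finite(vals)] <- 0
  dimnames(vals) <- list(colnames(E), paste0("F", seq_len(ncol(H))))
  structure(list(values = vals, method = method, cell_type = cell_type,
                 constant_genes = colnames(E)[constant]),
            class = "FactorGeneAssociation")
}

#' @export
print.FactorGeneAssociation <- function(x, ...) {
  cat(sprintf("FactorGeneAssociation (%s): %d genes x %d factors\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Top factor-associated genes
#'
#' @param assoc an [associate_genes()] result.
#' @param factor factor index or column name.
#' @param k number of genes (default 20; truncated with a warning if it
#'   exceeds the gene count).
#' @param sign `"positive"` for the largest scores, `"negative"` for the
#'   most negative. Ties are broken lexicographically by gene id.
#' @return character vector of gene ids in rank order.
#' @export
top_factor_genes <- function(assoc, factor = 1, k = 20,
                             sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  v <- assoc$values[, factor]
  if (k > length(v)) {
    warning("k truncated from ", k, " to ", length(v), " genes")
    k <- length(v)
  }
  key <- if (sign == "positive") -v else v
  ord <- order(key, names(v))
  names(v)[ord][seq_len(k)]
}

#' Load a ligand-receptor pair table
#'
#' Three-column TSV/CSV: `ligand`, `receptor`, `source`. Duplicate
#' (ligand, receptor) pairs are collapsed (sources concatenated).
#'
#' @param path pair table file.
#' @return An `LRDatabase` data frame with columns `ligand`, `receptor`,
#'   `source`.
#' @export
load_lr_database <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("LR database needs columns ligand, receptor")
  if (!"source" %in% names(df)) df$source <- NA_character_
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    df <- aggregate(source ~ ligand + receptor, df,
                    function(s) paste(unique(s), collapse = ";"))
  }
  structure(df[, c("ligand", "receptor", "source")],
            class = c("LRDatabase", "data.frame"))
}

#' Nominate ligand-receptor pairs consistent with a covarying factor pair
#'
#' For a covarying (sender factor, receiver factor) pair, retains database
#' pairs where the ligand is expressed (raw count > 0) in at least a
#' fraction `f_LR` of sender cells, the receptor in at least `f_LR` of
#' receiver cells, and both genes correlate with the respective factor at
#' absolute association `>= c_LR`. All four metrics are reported so
#' borderline candidates can be inspected; low cutoffs are recommended
#' since e.g. a constitutive receptor need not correlate with the factor.
#'
#' @param db an [load_lr_database()] table (or data frame with `ligand`,
#'   `receptor`).
#' @param sender_expr,receiver_expr cells x genes count matrices of the
#'   sender and receiver cell type (full transcriptome).
#' @param sender_assoc,receiver_assoc [associate_genes()] results for the
#'   two types.
#' @param sender_factor,receiver_factor the covarying factor (index or
#'   name) in each type.
#' @param f_LR minimum expressing-cell fraction (default 0.1).
#' @param c_LR minimum absolute factor association (default 0.1).
#' @return An `LRCandidateTable` data frame: `ligand`, `receptor`,
#'   `source`, `frac_ligand`, `frac_receptor`, `corr_ligand_factor`,
#'   `corr_receptor_factor`; one row per retained pair. Pairs whose genes
#'   are absent from the expression matrices are skipped.
#' @export
select_lr_pairs <- function(db, sender_expr, receiver_expr, sender_assoc,
                            receiver_assoc, sender_factor = 1,
                            receiver_factor = 1, f_LR = 0.1, c_LR = 0.1) {
  sender_expr <- as.matrix(strip_cm(sender_expr))
  receiver_expr <- as.matrix(strip_cm(receiver_expr))
  out <- data.frame(ligand = character(), receptor = character(),
                    source = character(), frac_ligand = numeric(),
                    frac_receptor = numeric(),
                    corr_ligand_factor = numeric(),
                    corr_receptor_factor = numeric())
  for (r in seq_len(nrow(db))) {
    lig <- db$ligand[r]; rec <- db$receptor[r]
    if (!(lig %in% colnames(sender_expr)) ||
        !(rec %in% colnames(receiver_expr)) ||
        !(lig %in% rownames(sender_assoc$values)) ||
        !(rec %in% rownames(receiver_assoc$values)))
      next
    fl <- mean(sender_expr[, lig] > 0)
    fr <- mean(receiver_expr[, rec] > 0)
    cl <- sender_assoc$values[lig, sender_factor]
    cr <- receiver_assoc$values[rec, receiver_factor]
    if (fl >= f_LR && fr >= f_LR && abs(cl) >= c_LR && abs(cr) >= c_LR) {
      out <- rbind(out, data.frame(
        ligand = lig, receptor = rec,
        source = if ("source" %in% names(db)) db$source[r] else NA_character_,
        frac_ligand = fl, frac_receptor = fr,
        corr_ligand_factor = unname(cl), corr_receptor_factor = unname(cr)))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("LRCandidateTable", "data.frame"))
}
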