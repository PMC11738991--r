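#' Read a gene-by-cell count matrix
#'
#' Reads either a 10x-style MatrixMarket triplet directory
#' (\code{matrix.mtx[.gz]}, \code{features.tsv[.gz]} or
#' \code{genes.tsv[.gz]}, \code{barcodes.tsv[.gz]}) or a dense CSV with gene
#' symbols as row names and cell barcodes as column headers.
#'
#' Duplicate gene symbols are disambiguated by suffixing \code{".1"},
#' \code{".2"}, ... in order of appearance. Counts must be non-negative
#' integers.
#'
#' @param path Directory containing an MTX triplet, or path to a dense CSV
#'   file (genes as rows).
#' @param sample_id Label attached to the matrix; defaults to the file or
#'   directory name.
#' @return A \code{count_matrix} object: a sparse \code{dgCMatrix}
#'   (genes x cells) with a \code{sample_id} attribute.
#' @export
read_count_matrix <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- basename(sub("/+$", "", path))
  if (dir.exists(path)) {
    find1 <- function(stems) {
      for (s in stems) for (ext in c("", ".gz")) {
        f <- file.path(path, paste0(s, ext))
        if (file.exists(f)) return(f)
      }
      NULL
    }
    mtx <- find1("matrix.mtx")
    feats <- find1(c("features.tsv", "genes.tsv"))
    bcs <- find1("barcodes.tsv")
    missing <- c(if (is.null(mtx)) "matrix.mtx",
                 if (is.null(feats)) "features.tsv/genes.tsv",
                 if (is.null(bcs)) "barcodes.tsv")
    if (length(missing))
      stop_format("MTX triplet incomplete in '", path, "': missing ",
                  paste(missing, collapse = ", "))
    m <- Matrix::readMM(mtx)
    ft <- read.delim(feats, header = FALSE, stringsAsFactors = FALSE)
    # 10x features.tsv: id, symbol, type; plain genes.tsv may have one column
    genes <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    barcodes <- read.delim(bcs, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop_format("MTX dimensions (", nrow(m), " x ", ncol(m),
                  ") do not match features (", length(genes),
                  ") / barcodes (", length(barcodes), ")")
  } else if (file.exists(path)) {
    df <- read.csv(path, row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    barcodes <- colnames(m)
  } else {
    stop_format("path does not exist: ", path)
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (any(vals < 0) || any(vals != round(vals)))
    stop_validation("count matrix contains negative or non-integer entries")
  new_count_matrix(m, make_unique_symbols(genes), barcodes, sample_id)
}

#' Construct a count matrix in memory
#'
#' @param counts Matrix (dense or sparse) of non-negative integer counts,
#'   genes x cells.
#' @param genes Gene symbols (duplicates disambiguated as in
#'   [read_count_matrix()]).
#' @param barcodes Unique cell identifiers.
#' @param sample_id Sample label.
#' @return Sparse \code{dgCMatrix} with dimnames and a \code{sample_id}
#'   attribute.
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         barcodes = colnames(counts),
                         sample_id = "sample") {
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(vals < 0) || any(vals != round(vals)))
    stop_validation("count matrix contains negative or non-integer entries")
  new_count_matrix(counts, make_unique_symbols(genes), barcodes, sample_id)
}

new_count_matrix <- function(m, genes, barcodes, sample_id) {
  if (anyDuplicated(barcodes))
    stop_validation("duplicate cell barcodes in sample '", sample_id, "'")
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix")
  dimnames(m) <- list(genes, barcodes)
  attr(m, "sample_id") <- sample_id
  m
}

#' Sample label of a count matrix
#' @param m A count matrix read by [read_count_matrix()] or built by
#'   [simulate_dataset()].
#' @return The sample identifier string.
#' @export
sample_id <- function(m) attr(m, "sample_id")

make_unique_symbols <- function(genes) {
  genes <- as.character(genes)
  dup <- duplicated(genes)
  if (!any(dup)) return(genes)
  counts <- new.env()
  vapply(genes, function(g) {
    k <- if (is.null(counts[[g]])) 0L else counts[[g]]
    counts[[g]] <- k + 1L
    if (k == 0L) g else paste0(g, ".", k)
  }, character(1), USE.NAMES = FALSE)
}

#' Read Cell Ranger style VDJ contig annotations
#'
#' Parses a \code{filtered_contig_annotations.csv}-dialect table into a
#' clonotype table. Non-productive contigs and chains other than TRA/TRB are
#' dropped. A barcode may legitimately carry two productive TRA rows plus one
#' TRB row (dual-alpha T cells). The clonotype identifier is taken from
#' \code{raw_clonotype_id} when present and non-empty; otherwise it is
#' synthesized per barcode as the sorted concatenation of
#' (chain, cdr3_nt, v_gene, j_gene) tuples.
#'
#' @param path CSV file with at least columns \code{barcode}, \code{chain},
#'   \code{cdr3}, \code{cdr3_nt}, \code{v_gene}, \code{j_gene},
#'   \code{productive}, \code{raw_clonotype_id}.
#' @return A data.frame with columns \code{barcode}, \code{clonotype_id},
#'   \code{chain}, \code{cdr3_nt}, \code{cdr3_aa}, \code{v_gene},
#'   \code{j_gene}, \code{productive}.
#' @export
read_contig_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene",
                "productive", "raw_clonotype_id")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_format("contig annotation file missing required column(s): ",
                paste(miss, collapse = ", "))
  keep <- df$productive %in% c(TRUE, "true", "True", "TRUE") &
    df$chain %in% c("TRA", "TRB")
  df <- df[keep, , drop = FALSE]
  out <- data.frame(barcode = df$barcode,
                    clonotype_id = df$raw_clonotype_id,
                    chain = df$chain,
                    cdr3_nt = df$cdr3_nt,
                    cdr3_aa = df$cdr3,
                    v_gene = df$v_gene,
                    j_gene = df$j_gene,
                    productive = TRUE,
                    stringsAsFactors = FALSE)
  need_id <- is.na(out$clonotype_id) | out$clonotype_id == ""
  if (any(need_id)) {
    for (bc in unique(out$barcode[need_id])) {
      i <- out$barcode == bc
      tup <- paste(out$chain[i], out$cdr3_nt[i], out$v_gene[i],
                   out$j_gene[i], sep = ":")
      out$clonotype_id[i & need_id] <- paste(sort(tup), collapse = ";")
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a flow-cytometry TCR reactivity table
#'
#' Each row is one tested TCR with CD107a degranulation percentages measured
#' in four conditions (TCR-transfected T cells vs tumor line / unstimulated,
#' mock-electroporated vs tumor line / unstimulated) plus the percentage of
#' cells expressing the murine-constant-domain marker of the transgenic TCR
#' (mTCRbeta). Percentages stay on the printed 0-100 scale.
#'
#' @param path CSV file with columns \code{tcr_id}, \code{clonotype_id},
#'   \code{pct_cd107a_vs_line}, \code{pct_cd107a_unstim},
#'   \code{pct_cd107a_mock_vs_line}, \code{pct_cd107a_mock_unstim},
#'   \code{pct_mtcrb}.
#' @return data.frame of assay rows.
#' @export
read_reactivity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tcr_id", "clonotype_id", "pct_cd107a_vs_line",
                "pct_cd107a_unstim", "pct_cd107a_mock_vs_line",
                "pct_cd107a_mock_unstim", "pct_mtcrb")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_format("reactivity table missing required column(s): ",
                paste(miss, collapse = ", "))
  pct_cols <- required[3:7]
  for (cc in pct_cols) {
    v <- as.numeric(df[[cc]])
    if (nrow(df) && (anyNA(v) || any(v < 0 | v > 100)))
      stop_validation("column '", cc, "' has percentages outside [0, 100]")
    df[[cc]] <- v
  }
  df
}

#' Write per-clonotype reactivity scores to CSV
#'
#' Rows are ordered by descending mean probability, ties broken
#' alphabetically by clonotype id, so output files are deterministic.
#'
#' @param scores data.frame as returned by [call_reactive()] (columns
#'   \code{clonotype_id}, \code{n_cells}, \code{mean_probability},
#'   \code{threshold}, \code{call}).
#' @param path Output CSV path.
#' @return Invisibly, the ordered data.frame that was written.
#' @export
write_clonotype_scores <- function(scores, path) {
  if (!nrow(scores)) stop_validation("no clonotype scores to write")
  ord <- order(-scores$mean_probability, scores$clonotype_id)
  out <- scores[ord, c("clonotype_id", "n_cells", "mean_probability",
                       "threshold", "call"), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a signature gene list file
#'
#' One gene symbol per line; a leading \code{-} marks a negatively
#' contributing gene. Blank lines and \code{#} comments are ignored.
#'
#' @param path Text file path.
#' @param name Signature name (defaults to file name).
#' @param method Scoring method: one of \code{"ssgsea"}, \code{"additive"},
#'   \code{"module"}, \code{"rank_u"}.
#' @return A \code{gene_signature} list with elements \code{name},
#'   \code{positive}, \code{negative}, \code{method}.
#' @export
read_signature <- function(path, name = NULL, method = "ssgsea") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  neg <- startsWith(lines, "-")
  gene_signature(name = if (is.null(name)) basename(path) else name,
                 positive = lines[!neg],
                 negative = sub("^-", "", lines[neg]),
                 method = method)
}

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param positive Character vector of positively contributing gene symbols.
#' @param negative Optional negatively contributing symbols.
#' @param method Scoring method (see [read_signature()]).
#' @return A \code{gene_signature} list.
#' @export
gene_signature <- function(name, positive, negative = character(),
                           method = c("ssgsea", "additive", "module",
                                      "rank_u")) {
  method <- match.arg(method)
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (!length(positive))
    stop_validation("signature '", name, "' has no positive genes")
  if (length(intersect(positive, negative)))
    stop_validation("signature '", name,
                    "' lists gene(s) as both positive and negative")
  structure(list(name = name, positive = positive, negative = negative,
                 method = method), class = "gene_signature")
}
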