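#' Directional gene signatures and plain gene lists
#'
#' A \code{GeneSignature} holds the up- and down-regulated gene symbols of a
#' directional signature (e.g. a senescence signature with 33 up and 67 down
#' genes, or an exhaustion marker set with up genes only). A \code{GeneList}
#' is an undirected set of symbols, used for housekeeping and universe lists.
#'
#' Symbols are upper-cased on construction by default so that human
#' (\code{CDKN1A}) and mouse (\code{Cdkn1a}) capitalization match the same
#' signature; set \code{case_sensitive = TRUE} to disable.
#'
#' @param name signature label.
#' @param up_genes,down_genes character vectors of gene symbols; one of the
#'   two may be empty.
#' @param case_sensitive keep symbol case as given instead of upper-casing.
#' @return an object of class \code{GeneSignature} with fields \code{name},
#'   \code{up_genes}, \code{down_genes}, \code{case_sensitive}.
#' @examples
#' gene_signature("toy", up_genes = c("MKI67"), down_genes = c("CDKN1A"))
#' @export
gene_signature <- function(name, up_genes = character(), down_genes = character(),
                           case_sensitive = FALSE) {
  norm <- function(x) {
    x <- as.character(x)
    x <- x[nzchar(x)]
    if (!case_sensitive) x <- toupper(x)
    x
  }
  up <- norm(up_genes); dn <- norm(down_genes)
  if (anyDuplicated(up)) {
    warnf("signature '%s': %d duplicate up-gene symbol(s) removed", name,
          sum(duplicated(up)))
    up <- unique(up)
  }
  if (anyDuplicated(dn)) {
    warnf("signature '%s': %d duplicate down-gene symbol(s) removed", name,
          sum(duplicated(dn)))
    dn <- unique(dn)
  }
  both <- intersect(up, dn)
  if (length(both))
    stopf("signature '%s': symbol(s) in both directions: %s", name,
          paste(both, collapse = ", "))
  if (!length(up) && !length(dn))
    stopf("signature '%s' is empty", name)
  structure(list(name = name, up_genes = up, down_genes = dn,
                 case_sensitive = case_sensitive),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d up, %d down\n", x$name,
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' @rdname gene_signature
#' @param genes character vector of symbols.
#' @export
gene_list <- function(name, genes, case_sensitive = FALSE) {
  g <- as.character(genes)
  g <- g[nzchar(g)]
  if (!case_sensitive) g <- toupper(g)
  g <- unique(g)
  if (!length(g)) stopf("gene list '%s' is empty", name)
  structure(list(name = name, genes = g, case_sensitive = case_sensitive),
            class = "GeneList")
}

#' Load a directional gene signature from a file
#'
#' Two dialects are supported. \code{gmt_directional}: a GMT file (tab
#' separated: set name, description, genes...) containing two lines named
#' \code{<sig>_UP} and \code{<sig>_DN}; a signature with only one line is
#' accepted and the missing direction is empty. \code{two_column}: a CSV/TSV
#' with columns \code{gene} and \code{direction} (values \code{up} or
#' \code{down}), header optional.
#'
#' @param path file path.
#' @param dialect \code{"gmt_directional"} or \code{"two_column"}.
#' @param name optional signature name; default is derived from the set names
#'   (GMT) or the file name (two-column).
#' @param case_sensitive passed to \code{\link{gene_signature}}.
#' @return a validated \code{GeneSignature}.
#' @export
load_signature <- function(path, dialect = c("gmt_directional", "two_column"),
                           name = NULL, case_sensitive = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("signature file not found: %s", path)
  if (dialect == "gmt_directional") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stopf("empty GMT file: %s", path)
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stopf("unparseable GMT line (need name, description, >=1 gene): %s",
                               substr(l, 1, 60))
      list(name = f[1], genes = f[-(1:2)])
    })
    nms <- vapply(sets, `[[`, "", "name")
    is_up <- grepl("_UP$", nms, ignore.case = TRUE)
    is_dn <- grepl("_DN$|_DOWN$", nms, ignore.case = TRUE)
    if (sum(is_up) > 1 || sum(is_dn) > 1)
      stopf("GMT file has multiple _UP or _DN sets: %s", path)
    if (!any(is_up) && !any(is_dn))
      stopf("GMT file has no *_UP / *_DN set: %s", path)
    up <- if (any(is_up)) sets[[which(is_up)]]$genes else character()
    dn <- if (any(is_dn)) sets[[which(is_dn)]]$genes else character()
    base <- sub("_(UP|DN|DOWN)$", "", nms[which(is_up | is_dn)[1]],
                ignore.case = TRUE)
    gene_signature(name %||% base, up, dn, case_sensitive = case_sensitive)
  } else {
    df <- utils::read.table(path, sep = guess_sep(path), header = FALSE,
                            stringsAsFactors = FALSE, strip.white = TRUE)
    if (ncol(df) < 2) stopf("two_column file needs gene and direction columns: %s", path)
    df <- df[, 1:2]
    names(df) <- c("gene", "direction")
    # drop a header row if present
    if (tolower(df$gene[1]) %in% c("gene", "symbol", "gene_symbol"))
      df <- df[-1, , drop = FALSE]
    dirv <- tolower(trimws(df$direction))
    bad <- !dirv %in% c("up", "down", "dn")
    if (any(bad))
      stopf("unparseable direction value(s): %s",
            paste(unique(df$direction[bad]), collapse = ", "))
    gene_signature(name %||% sub("\\.[^.]*$", "", basename(path)),
                   up_genes = df$gene[dirv == "up"],
                   down_genes = df$gene[dirv %in% c("down", "dn")],
                   case_sensitive = case_sensitive)
  }
}

guess_sep <- function(path) {
  l <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", l)) "\t" else ","
}

#' Write a signature back to GMT (directional dialect)
#'
#' @param sig a \code{GeneSignature}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "GeneSignature"))
  lines <- character()
  if (length(sig$up_genes))
    lines <- c(lines, paste(c(paste0(toupper(sig$name), "_UP"), sig$name,
                              sig$up_genes), collapse = "\t"))
  if (length(sig$down_genes))
    lines <- c(lines, paste(c(paste0(toupper(sig$name), "_DN"), sig$name,
                              sig$down_genes), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load an undirected gene list (one symbol per line, or first column)
#'
#' @inheritParams load_signature
#' @export
load_gene_list <- function(path, name = NULL, case_sensitive = FALSE) {
  if (!file.exists(path)) stopf("gene list file not found: %s", path)
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)[[1]]
  gene_list(name %||% sub("\\.[^.]*$", "", basename(path)), x,
            case_sensitive = case_sensitive)
}

#' Coverage of a signature in a gene universe
#'
#' Reports, per direction, the fraction of signature genes present in a
#' universe (e.g. the rownames of an expression matrix) and the missing
#' symbols. Never mutates the signature; zero coverage is a valid report.
#'
#' @param sig a \code{GeneSignature}.
#' @param universe a \code{GeneList} or character vector of symbols.
#' @return a list with \code{coverage_up}, \code{coverage_down},
#'   \code{coverage} (overall), \code{missing_up}, \code{missing_down}.
#' @export
validate_against_universe <- function(sig, universe) {
  stopifnot(inherits(sig, "GeneSignature"))
  uni <- if (inherits(universe, "GeneList")) universe$genes
         else unique(toupper(as.character(universe)))
  if (!length(uni)) stopf("empty universe")
  cov1 <- function(g) if (!length(g)) NA_real_ else mean(g %in% uni)
  all_g <- c(sig$up_genes, sig$down_genes)
  list(coverage_up = cov1(sig$up_genes),
       coverage_down = cov1(sig$down_genes),
       coverage = mean(all_g %in% uni),
       missing_up = setdiff(sig$up_genes, uni),
       missing_down = setdiff(sig$down_genes, uni))
}

#' Default housekeeping gene list
#'
#' A compact set of constitutively expressed human genes used by
#' \code{\link{housekeeping_filter}} when no list is supplied. Any study
#' should override it with its own curated list via \code{hk}.
#'
#' @return a \code{GeneList}.
#' @export
default_housekeeping <- function() {
  gene_list("housekeeping_default",
            c("ACTB", "GAPDH", "B2M", "RPL13A", "RPLP0", "TBP", "UBC",
              "PPIA", "HPRT1", "PGK1", "SDHA", "YWHAZ", "GUSB", "TFRC"))
}
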