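#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (term, description,
#'   members...).
#' @return Named list of character vectors of member gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Map a probe list to unique gene symbols
#'
#' Genes interrogated by more than one CpG probe are listed only once.
#'
#' @param probes Character vector of probe ids.
#' @param manifest Probe manifest with \code{probe_id} and
#'   \code{gene_symbol}.
#' @return Character vector of unique gene symbols, in first-probe order.
#' @export
dedupe_genes <- function(probes, manifest) {
  if (length(probes) == 0L) return(character())
  idx <- match(probes, manifest$probe_id)
  if (anyNA(idx)) {
    stop("manifest missing probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5L), collapse = ", "))
  }
  unique(manifest$gene_symbol[idx])
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of the query gene list
#' against a gene background (typically all genes surviving probe
#' filtering). Terms are intersected with the background before testing;
#' terms disjoint from the background are skipped and reported. The p-value
#' is the one-sided hypergeometric upper-tail probability of an overlap at
#' least as large as observed (optionally the EASE variant that deflates the
#' observed overlap by one); q-values are Benjamini-Hochberg across the
#' tested terms.
#'
#' @param gene_list Character vector of query genes, a subset of
#'   \code{background}.
#' @param annotation Named list of term member vectors (see
#'   \code{\link{read_gmt}}).
#' @param background Character vector, the gene universe.
#' @param ease Use the EASE-adjusted overlap (observed minus one); default
#'   \code{FALSE}, the plain hypergeometric.
#' @param alpha FDR threshold used for the \code{significant} flag.
#' @return Data frame with \code{term}, \code{overlap}, \code{list_size},
#'   \code{term_size}, \code{background_size}, \code{raw_p}, \code{q},
#'   \code{significant}, sorted by \code{q}; skipped terms in the
#'   \code{"skipped"} attribute.
#' @export
enrich <- function(gene_list, annotation, background, ease = FALSE,
                   alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("background must be non-empty")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background)) {
    stop("gene_list must be a subset of the background")
  }
  n_bg <- length(background)
  n_list <- length(gene_list)
  terms <- lapply(annotation, function(g) intersect(unique(g), background))
  skipped <- names(terms)[lengths(terms) == 0L]
  terms <- terms[lengths(terms) > 0L]
  if (length(terms) == 0L) {
    out <- data.frame(term = character(), overlap = integer(),
                      list_size = integer(), term_size = integer(),
                      background_size = integer(), raw_p = numeric(),
                      q = numeric(), significant = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  rows <- lapply(names(terms), function(tn) {
    members <- terms[[tn]]
    ov <- length(intersect(gene_list, members))
    k <- length(members)
    x <- if (ease) max(ov - 1L, 0L) else ov
    p <- stats::phyper(x - 1L, k, n_bg - k, n_list, lower.tail = FALSE)
    data.frame(term = tn, overlap = ov, list_size = n_list, term_size = k,
               background_size = n_bg, raw_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$raw_p)
  out$significant <- out$q < alpha
  out <- out[order(out$q, out$raw_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
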