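write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic dataset as the standard pipeline inputs
#'
#' Emits the long-format intensity table (sample_id, probe_id, cy5, cy3,
#' detection_p), the replicate map, probe manifest, sample annotation,
#' expression matrix and truth labels as TSV files under \code{dir}.
#'
#' @param ds A dataset from \code{\link{generate_dataset}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ints <- ds$intensities
  long <- data.frame(
    sample_id = rep(colnames(ints$cy5), each = nrow(ints$cy5)),
    probe_id = rep(rownames(ints$cy5), ncol(ints$cy5)),
    cy5 = as.vector(ints$cy5),
    cy3 = as.vector(ints$cy3),
    detection_p = as.vector(ints$detection_p),
    stringsAsFactors = FALSE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    replicate_map = file.path(dir, "replicate_map.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_tsv(long, paths["intensities"])
  write_tsv(ints$replicate_map, paths["replicate_map"])
  write_tsv(ds$manifest, paths["manifest"])
  write_tsv(ds$annotation, paths["annotation"])
  write_tsv(ds$expression, paths["expression"], rownames_as = "gene")
  truth <- data.frame(tumor_id = names(ds$truth$cluster),
                      cluster = unname(ds$truth$cluster),
                      stringsAsFactors = FALSE)
  write_tsv(truth, paths["truth"])
  invisible(paths)
}

#' Read a long-format intensity table into a raw intensity set
#'
#' @param intensities_path TSV with columns sample_id, probe_id, cy5, cy3,
#'   detection_p.
#' @param replicate_map_path TSV with columns sample_id, tumor_id.
#' @return A raw intensity set: matrices \code{cy5}, \code{cy3},
#'   \code{detection_p} (probes x samples) and \code{replicate_map}.
#' @export
read_intensities <- function(intensities_path, replicate_map_path) {
  long <- read_tsv(intensities_path)
  need <- c("sample_id", "probe_id", "cy5", "cy3", "detection_p")
  if (!all(need %in% names(long))) {
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  }
  probes <- unique(long$probe_id)
  samples <- unique(long$sample_id)
  mk <- function(v) {
    m <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
    m[cbind(match(long$probe_id, probes), match(long$sample_id, samples))] <- v
    m
  }
  list(cy5 = mk(long$cy5), cy3 = mk(long$cy3),
       detection_p = mk(long$detection_p),
       replicate_map = read_tsv(replicate_map_path))
}

#' Read a wide beta matrix (rows = probes, columns = samples)
#' @param path TSV whose first column holds probe ids.
#' @return Numeric probes x samples matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Validate pipeline input files
#'
#' Schema and content checks with row-level diagnostics: required columns,
#' duplicate probe ids in the manifest, beta values outside \code{[0, 1]}
#' (reported with probe/sample coordinates), detection p-values outside
#' \code{[0, 1]}, and duplicate sample/tumor assignments in the replicate
#' map.
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   \code{beta}, \code{manifest}, \code{annotation}, \code{intensities},
#'   \code{replicate_map}. Missing files are themselves reported.
#' @return Character vector of problem descriptions; empty when clean.
#' @export
validate_inputs <- function(paths) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) note("missing file '%s': %s", nm, paths[[nm]])
  }
  if (length(problems) > 0L) return(problems)

  if (!is.null(paths$manifest)) {
    man <- read_tsv(paths$manifest)
    need <- c("probe_id", "gene_symbol", "snp_repeat_flag")
    if (!all(need %in% names(man))) {
      note("manifest lacks columns: %s",
           paste(setdiff(need, names(man)), collapse = ", "))
    } else if (anyDuplicated(man$probe_id)) {
      note("duplicate probe_id in manifest: %s",
           paste(unique(man$probe_id[duplicated(man$probe_id)]), collapse = ", "))
    }
  }
  if (!is.null(paths$beta)) {
    beta <- read_beta_matrix(paths$beta)
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
    for (i in seq_len(min(nrow(bad), 20L))) {
      note("beta value %.4g out of [0,1] at probe %s, sample %s",
           beta[bad[i, 1], bad[i, 2]],
           rownames(beta)[bad[i, 1]], colnames(beta)[bad[i, 2]])
    }
    if (anyDuplicated(rownames(beta))) note("duplicate probe ids in beta matrix")
  }
  if (!is.null(paths$annotation)) {
    ann <- read_tsv(paths$annotation)
    if (!"tumor_id" %in% names(ann)) note("annotation lacks tumor_id")
    else if (anyDuplicated(ann$tumor_id)) note("duplicate tumor_id in annotation")
  }
  if (!is.null(paths$replicate_map)) {
    rm_ <- read_tsv(paths$replicate_map)
    if (!all(c("sample_id", "tumor_id") %in% names(rm_))) {
      note("replicate map needs sample_id and tumor_id columns")
    } else if (anyDuplicated(rm_$sample_id)) {
      note("sample_id appears in more than one replicate-map row")
    }
  }
  problems
}
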