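# Table/FASTA readers and writers. All tables are TSV; '#' comment lines and
# blank lines are skipped; peptides are upper-cased on read; malformed rows
# fail with file:line diagnostics.

.schemas <- list(
  ba = list(cols = c("peptide", "allele", "ic50_nM"),
            numeric = "ic50_nM", upper = "peptide"),
  el = list(cols = c("peptide", "alleles", "label"),
            numeric = "label", upper = "peptide"),
  pseudo = list(cols = c("allele", "pseudo_sequence"),
                numeric = character(0), upper = "pseudo_sequence"),
  mutations = list(cols = c("protein_id", "wildtype_seq", "mutant_seq",
                            "mutation_type", "altered_pos"),
                   numeric = "altered_pos",
                   upper = c("wildtype_seq", "mutant_seq")),
  training = list(cols = c("peptide", "allele", "label", "provenance", "fold"),
                  numeric = c("label", "fold"), upper = "peptide"),
  predictions = list(cols = c("peptide", "allele", "score"),
                     numeric = "score", upper = "peptide", variadic = TRUE)
)

#' Read a schema-validated TSV table
#'
#' @param path File path.
#' @param schema One of `"ba"`, `"el"`, `"pseudo"`, `"mutations"`,
#'   `"training"`, `"predictions"`; fixes the expected columns. A header line
#'   naming the columns is optional.
#' @param allow_empty Allow missing fields (used by the mutation tables,
#'   where missing values are filtered later rather than rejected).
#' @return A data.frame with the schema's columns.
#' @export
read_table <- function(path, schema, allow_empty = schema == "mutations") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- .schemas[[schema]]
  if (is.null(spec)) stop("unknown schema: ", schema, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                            length(spec$cols)), spec$cols))
  } else {
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (identical(tolower(utils::head(parts[[1]], length(spec$cols))),
                  tolower(spec$cols))) {
      keep <- keep[-1]; parts <- parts[-1]
    }
    nc <- lengths(parts)
    bad <- if (isTRUE(spec$variadic)) which(nc < length(spec$cols)) else
      which(nc != length(spec$cols))
    if (length(bad)) {
      stop(sprintf("%s:%d: expected %d tab-separated columns (%s), found %d",
                   path, keep[bad[1]], length(spec$cols),
                   paste(spec$cols, collapse = ", "), nc[bad[1]]),
           call. = FALSE)
    }
    if (isTRUE(spec$variadic)) {
      # trailing per-fold score columns are allowed; keep the fixed ones
      parts <- lapply(parts, `[`, seq_len(length(spec$cols)))
    }
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- spec$cols
  }
  for (cn in spec$numeric) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & df[[cn]] != "NA" &
                   !(allow_empty & df[[cn]] == ""))
    if (length(bad)) {
      stop(sprintf("%s:%d: column '%s' is not numeric ('%s')",
                   path, keep[bad[1]], cn, df[[cn]][bad[1]]), call. = FALSE)
    }
    df[[cn]] <- v
  }
  for (cn in spec$upper) df[[cn]] <- toupper(df[[cn]])
  if (!allow_empty) {
    for (cn in setdiff(spec$cols, spec$numeric)) {
      bad <- which(!nzchar(df[[cn]]))
      if (length(bad)) {
        stop(sprintf("%s:%d: empty field in column '%s'", path, keep[bad[1]],
                     cn), call. = FALSE)
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a TSV table with header
#'
#' Round-trips with [read_table()] for the matching schema.
#'
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read an eluted-ligand table
#'
#' TSV `peptide<TAB>allele1,allele2,...<TAB>label`. The candidate-allele
#' column is split on commas.
#'
#' @param path File path.
#' @return Data.frame with columns `peptide`, `alleles` (list column of
#'   candidate-allele character vectors), `label`.
#' @export
read_el_table <- function(path) {
  df <- read_table(path, schema = "el")
  df$alleles <- strsplit(df$alleles, ",", fixed = TRUE)
  df$label <- as.integer(df$label)
  df
}

#' Read protein sequences from FASTA
#'
#' Standard FASTA (wrapped or unwrapped); sequences upper-cased.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Top-level keys are [model_config()] arguments plus optional `curation`
#' (threshold, rounds) and path entries; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param overrides Named list overriding file values (CLI flags).
#' @return List with elements `model` (a `model_config`) and `options`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  extra <- setdiff(names(raw), c(names(formals(model_config)),
                                 "curation", "paths", "folds", "panel"))
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  model_args <- raw[intersect(names(raw), names(formals(model_config)))]
  list(model = do.call(model_config, model_args),
       options = raw[setdiff(names(raw), names(model_args))])
}

# Run manifest: config, seed, input checksums, package version.
write_manifest <- function(path, config, seed, inputs = character(0)) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "mhcbind",
                   version = as.character(utils::packageVersion("mhcbind")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, config = unclass(config),
                   input_md5 = checksums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
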