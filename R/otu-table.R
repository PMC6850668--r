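#' Construct an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix of read counts with OTUs as
#' rows and samples as columns. Row and column names are the OTU and sample
#' identifiers and must be unique.
#'
#' @param counts numeric matrix of non-negative integer-valued counts, with
#'   unique rownames (OTU ids) and colnames (sample ids).
#' @return an object of class `otu_table` (an integer matrix).
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 3L, 0L), nrow = 3,
#'             dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
#' tab <- otu_table(m)
#' otu_ids(tab)
#' sample_ids(tab)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) {
    pc_stop("paircomm_bad_counts", "counts must be a matrix")
  }
  validate_counts(counts)
  ids_r <- rownames(counts)
  ids_c <- colnames(counts)
  if (is.null(ids_r) || is.null(ids_c)) {
    pc_stop("paircomm_bad_counts", "counts must have OTU rownames and sample colnames")
  }
  if (anyDuplicated(ids_r)) {
    pc_stop("paircomm_duplicate_ids", "duplicate OTU ids: %s",
            paste(unique(ids_r[duplicated(ids_r)]), collapse = ", "))
  }
  if (anyDuplicated(ids_c)) {
    pc_stop("paircomm_duplicate_ids", "duplicate sample ids: %s",
            paste(unique(ids_c[duplicated(ids_c)]), collapse = ", "))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", class(matrix())))
}

validate_counts <- function(counts) {
  if (anyNA(counts)) {
    pc_stop("paircomm_bad_counts", "counts contain missing values")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    pc_stop("paircomm_bad_counts", "negative count at row %s, column %s",
            bad[1], bad[2])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    pc_stop("paircomm_bad_counts",
            "non-integer count %s at row %s (%s), column %s (%s)",
            counts[bad[1], bad[2]], bad[1],
            rownames(counts)[bad[1]] %||% "?", bad[2],
            colnames(counts)[bad[2]] %||% "?")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# ---- file input/output ------------------------------------------------------

#' Read and write OTU tables
#'
#' The tab-separated dialect has a header row whose first field is `#OTU_ID`
#' followed by the sample ids, and one row per OTU. BIOM-format files
#' (JSON dialect) are accepted as an alternative input when the
#' \pkg{biomformat} package is available.
#'
#' @param path file path. Files ending in `.biom` are read as BIOM.
#' @return [read_otu_table()] returns an [otu_table()];
#'   [write_otu_table()] returns `path`, invisibly.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) {
    pc_stop("paircomm_missing_file", "file not found: %s", path)
  }
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      pc_stop("paircomm_missing_file",
              "the biomformat package is required to read %s", path)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    pc_stop("paircomm_duplicate_ids", "duplicate sample ids in %s: %s", path,
            paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    pc_stop("paircomm_bad_counts", "OTU table %s has no sample columns", path)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    pc_stop("paircomm_bad_counts", "non-numeric counts in %s", path)
  }
  rownames(m) <- ids
  otu_table(m)
}

#' @rdname read_otu_table
#' @param table an [otu_table()].
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(`#OTU_ID` = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with named header columns `sample_id`, `island`, `pit`,
#' `depth_cm`, `pool` and optionally `replicate`.
#'
#' @param path file path.
#' @return a data.frame of per-sample factors.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    pc_stop("paircomm_missing_file", "file not found: %s", path)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_metadata(df)
  df
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "island", "pit", "depth_cm", "pool")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    pc_stop("paircomm_metadata_mismatch", "metadata lacks columns: %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    pc_stop("paircomm_duplicate_ids", "duplicate sample ids in metadata: %s",
            paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                  collapse = ", "))
  }
  if (!all(meta$pool %in% c("DNA", "RNA"))) {
    pc_stop("paircomm_metadata_mismatch", "pool must be DNA or RNA")
  }
  if (any(meta$depth_cm <= 0)) {
    pc_stop("paircomm_metadata_mismatch", "depth_cm must be positive")
  }
  invisible(TRUE)
}

#' Read a taxonomy table
#'
#' Tab-separated with columns `otu_id` then the seven ranks
#' `kingdom, phylum, subphylum, class, order, family, genus` (most to least
#' inclusive). Unidentified ranks carry the literal token
#' `unidentified__<rank>`; once a rank is unidentified all lower ranks must be
#' unidentified too.
#'
#' @param path file path.
#' @return a data.frame with `otu_id` and the seven rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    pc_stop("paircomm_missing_file", "file not found: %s", path)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_taxonomy(df)
  df
}

#' @rdname read_taxonomy
#' @format NULL
#' @export
tax_ranks <- c("kingdom", "phylum", "subphylum", "class", "order", "family",
               "genus")

validate_taxonomy <- function(tax) {
  miss <- setdiff(c("otu_id", tax_ranks), names(tax))
  if (length(miss)) {
    pc_stop("paircomm_metadata_mismatch", "taxonomy lacks columns: %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tax$otu_id)) {
    pc_stop("paircomm_duplicate_ids", "duplicate OTU ids in taxonomy")
  }
  unid <- sapply(tax_ranks, function(r) startsWith(tax[[r]], "unidentified__"))
  if (is.null(dim(unid))) unid <- matrix(unid, nrow = 1)
  # once unidentified, all lower ranks unidentified
  ok <- apply(unid, 1, function(z) all(diff(as.integer(z)) >= 0) ||
                all(!z) || all(z[which(z)[1]:length(z)]))
  if (!all(ok)) {
    pc_stop("paircomm_metadata_mismatch",
            "taxonomy row(s) %s have an identified rank below an unidentified one",
            paste(which(!ok), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a paired DNA/RNA dataset
#'
#' Reads and cross-validates an OTU table, its sample metadata and
#' (optionally) a taxonomy table. Samples present in the table but absent
#' from the metadata are an error.
#'
#' @param otu_table_path path to a TSV or BIOM OTU table.
#' @param metadata_path path to the sample metadata TSV.
#' @param taxonomy_path optional path to the taxonomy TSV.
#' @return a list with elements `table`, `metadata` and `taxonomy` (NULL when
#'   not supplied).
#' @export
read_paired_dataset <- function(otu_table_path, metadata_path,
                                taxonomy_path = NULL) {
  tab <- read_otu_table(otu_table_path)
  meta <- read_sample_metadata(metadata_path)
  missing <- setdiff(sample_ids(tab), meta$sample_id)
  if (length(missing)) {
    pc_stop("paircomm_metadata_mismatch",
            "samples in OTU table but not in metadata: %s",
            paste(missing, collapse = ", "))
  }
  tax <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  list(table = tab, metadata = meta, taxonomy = tax)
}

# ---- pooling, filtering, pairing -------------------------------------------

#' Pool replicate samples within each (island, pit, depth, pool) cell
#'
#' Replicate counts are summed, mirroring the wet-lab pooling of the five
#' soil-tube replicates; summation preserves the integer counts that
#' rarefaction needs. The pooled sample id is
#' `<island>.<pit>.D<depth_cm>.<pool>`.
#'
#' @param table an [otu_table()] whose samples carry replicate structure.
#' @param meta metadata with a populated `replicate` column.
#' @return list with the pooled `table` and pooled `metadata` (one row per
#'   cell, no replicate column).
#' @export
pool_replicates <- function(table, meta) {
  validate_metadata(meta)
  if (is.null(meta$replicate)) {
    pc_stop("paircomm_metadata_mismatch", "metadata lacks a replicate column")
  }
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  cell <- interaction(meta$island, meta$pit, meta$depth_cm, meta$pool,
                      drop = TRUE, lex.order = TRUE)
  key <- unique(data.frame(island = meta$island, pit = meta$pit,
                           depth_cm = meta$depth_cm, pool = meta$pool,
                           cell = as.character(cell),
                           stringsAsFactors = FALSE))
  pooled <- matrix(0L, nrow(table), nlevels(cell),
                   dimnames = list(rownames(table), levels(cell)))
  for (cl in levels(cell)) {
    pooled[, cl] <- rowSums(table[, cell == cl, drop = FALSE])
  }
  key <- key[match(colnames(pooled), key$cell), , drop = FALSE]
  ids <- sprintf("%s.%s.D%g.%s", key$island, key$pit, key$depth_cm, key$pool)
  colnames(pooled) <- ids
  meta_out <- data.frame(sample_id = ids, island = key$island, pit = key$pit,
                         depth_cm = key$depth_cm, pool = key$pool,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(table = otu_table(pooled), metadata = meta_out)
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples equals one; such reads
#' often represent sequencing error. The operation is idempotent and leaves
#' the sample set unchanged.
#'
#' @param table an [otu_table()].
#' @return the filtered [otu_table()].
#' @export
filter_singletons <- function(table) {
  keep <- rowSums(table) != 1L
  otu_table(table[keep, , drop = FALSE])
}

#' Pair pooled DNA and RNA samples
#'
#' One pair per (island, pit, depth) cell that has both nucleic-acid pools.
#' Cells missing one pool are reported with a warning and skipped; a cell
#' with two samples of the same pool is an error.
#'
#' @param meta pooled metadata (one sample per cell per pool).
#' @return a data.frame with columns `pair_id`, `dna_sample_id`,
#'   `rna_sample_id`, `island`, `pit`, `depth_cm`.
#' @export
pair_samples <- function(meta) {
  validate_metadata(meta)
  cell <- interaction(meta$island, meta$pit, meta$depth_cm, drop = TRUE,
                      lex.order = TRUE)
  out <- lapply(levels(cell), function(cl) {
    sub <- meta[cell == cl, , drop = FALSE]
    if (anyDuplicated(sub$pool)) {
      pc_stop("paircomm_duplicate_ids",
              "cell %s has more than one sample per pool", cl)
    }
    if (!all(c("DNA", "RNA") %in% sub$pool)) {
      pc_warn("cell %s lacks a %s sample; skipped", cl,
              setdiff(c("DNA", "RNA"), sub$pool))
      return(NULL)
    }
    data.frame(pair_id = cl,
               dna_sample_id = sub$sample_id[sub$pool == "DNA"],
               rna_sample_id = sub$sample_id[sub$pool == "RNA"],
               island = sub$island[1], pit = sub$pit[1],
               depth_cm = sub$depth_cm[1], stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    return(data.frame(pair_id = character(), dna_sample_id = character(),
                      rna_sample_id = character(), island = character(),
                      pit = character(), depth_cm = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
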