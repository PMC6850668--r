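#' Configuration for biogeographic range classification
#'
#' @param arctic_boundary latitude (decimal degrees) of the Arctic circle;
#'   records strictly north of it count as Arctic for the bipolar rule.
#'   Default 66.56.
#' @param antarctic_boundary latitude separating the Antarctic study region
#'   from "elsewhere". Default -60 (the Antarctic Treaty line). Records
#'   flagged as study sites never count as "elsewhere" regardless of
#'   latitude, so sub-Antarctic study islands north of the line (e.g. Bird
#'   Island at 54.0S) are handled by the flag, not the cut.
#' @return a `range_rule_config` list.
#' @export
range_rule_config <- function(arctic_boundary = 66.56,
                              antarctic_boundary = -60.0) {
  stopifnot(arctic_boundary > antarctic_boundary)
  structure(list(arctic_boundary = arctic_boundary,
                 antarctic_boundary = antarctic_boundary),
            class = "range_rule_config")
}

check_occurrences <- function(records) {
  need <- c("otu_id", "latitude")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    pc_stop("paircomm_metadata_mismatch", "occurrence table lacks columns: %s",
            paste(miss, collapse = ", "))
  }
  if (is.null(records$is_study_site)) records$is_study_site <- 0L
  if (any(records$latitude < -90 | records$latitude > 90)) {
    pc_stop("paircomm_metadata_mismatch", "latitudes must lie in [-90, 90]")
  }
  records
}

#' Classify one OTU's biogeographic range from occurrence latitudes
#'
#' An OTU detected in the Antarctic study is
#' \describe{
#'   \item{endemic}{if it has no occurrence record "elsewhere" (a non-study
#'     record north of the Antarctic boundary);}
#'   \item{bipolar}{if it occurs strictly north of the Arctic circle but at
#'     no latitude in between;}
#'   \item{cosmopolitan}{otherwise.}
#' }
#' "North of" the Arctic circle is a strict inequality, so a record exactly
#' on the boundary counts as mid-latitude. Bipolar takes precedence over
#' cosmopolitan; the three labels are mutually exclusive.
#'
#' @param records data.frame of occurrence records for a single OTU with
#'   columns `latitude` and optionally `is_study_site` (0/1).
#' @param config a [range_rule_config()].
#' @return one of `"endemic"`, `"cosmopolitan"`, `"bipolar"`.
#' @export
classify_otu <- function(records, config = range_rule_config()) {
  records <- as.data.frame(records)
  if (is.null(records$otu_id)) records$otu_id <- "?"
  records <- check_occurrences(records)
  antarctic <- records$is_study_site == 1 |
    records$latitude <= config$antarctic_boundary
  if (!any(antarctic)) {
    pc_stop("paircomm_not_in_study",
            "OTU has no Antarctic (study) occurrence record")
  }
  elsewhere <- records$latitude[!antarctic]
  if (length(elsewhere) == 0) {
    return("endemic")
  }
  arctic <- elsewhere > config$arctic_boundary
  if (any(arctic) && all(arctic)) "bipolar" else "cosmopolitan"
}

#' Classify every study OTU
#'
#' Study OTUs that are absent from the occurrence table (no match outside the
#' study at the clustering threshold) are endemic by definition: endemism is
#' membership in the Antarctic dataset without being "found at sites
#' elsewhere".
#'
#' @param records occurrence data.frame (`otu_id`, `latitude`,
#'   optional `is_study_site`).
#' @param study_otus character vector of study OTU ids.
#' @param config a [range_rule_config()].
#' @param taxonomy optional taxonomy data.frame; when given, the summary also
#'   counts labels per genus.
#' @return a list with `labels` (data.frame `otu_id`, `label`), `summary`
#'   (counts per label) and `genus_summary` (counts per genus and label, or
#'   NULL).
#' @export
classify_all <- function(records, study_otus, config = range_rule_config(),
                         taxonomy = NULL) {
  if (length(study_otus) == 0) {
    return(list(labels = data.frame(otu_id = character(),
                                    label = character()),
                summary = c(endemic = 0L, cosmopolitan = 0L, bipolar = 0L),
                genus_summary = NULL))
  }
  records <- check_occurrences(records)
  if (is.null(records$is_study_site)) records$is_study_site <- 0L
  by_otu <- split(records, factor(records$otu_id, levels = study_otus))
  label <- vapply(study_otus, function(o) {
    r <- by_otu[[o]]
    if (is.null(r) || nrow(r) == 0) return("endemic")
    # an OTU in the study community always has Antarctic evidence, even when
    # the occurrence table only holds its non-study hits
    r <- rbind(r, data.frame(otu_id = o, latitude = config$antarctic_boundary - 1,
                             is_study_site = 1L))
    classify_otu(r, config)
  }, character(1))
  labels <- data.frame(otu_id = study_otus, label = unname(label),
                       stringsAsFactors = FALSE)
  lev <- c("endemic", "cosmopolitan", "bipolar")
  summary <- table(factor(labels$label, levels = lev))
  gs <- NULL
  if (!is.null(taxonomy)) {
    gen <- taxonomy$genus[match(labels$otu_id, taxonomy$otu_id)]
    gen[is.na(gen)] <- "unidentified__genus"
    gs <- as.data.frame(table(genus = gen,
                              label = factor(labels$label, levels = lev)),
                        responseName = "n_otus", stringsAsFactors = FALSE)
  }
  list(labels = labels, summary = c(unclass(summary)), genus_summary = gs)
}

#' Read occurrence records from TSV
#'
#' Columns: `otu_id`, `latitude` (decimal degrees, positive north) and
#' `is_study_site` (0/1; study-site records never count as "elsewhere").
#'
#' @param path file path.
#' @return an occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    pc_stop("paircomm_missing_file", "file not found: %s", path)
  }
  check_occurrences(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
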