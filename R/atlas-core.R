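#' Map a fine tissue label onto its histopathology scoring group
#'
#' The two scoring systems tabulate their maxima at a coarse, two-group
#' granularity: colonic tissues (colon, rectum, caecum) versus ileal tissues
#' (ileum, ileocecal valve, small intestine, anastomosis, pouch).
#'
#' @param tissue character vector of fine tissue labels.
#' @return character vector over \code{"colon_group"} / \code{"ileum_group"}.
#' @examples
#' tissueGrouping(c("caecum", "pouch"))
#' @export
tissueGrouping <- function(tissue) {
  colonTissues <- c("colon", "rectum", "caecum")
  ileumTissues <- c("ileum", "ileocecal valve", "small intestine",
                    "anastomosis", "pouch")
  unknown <- setdiff(unique(tissue), c(colonTissues, ileumTissues))
  if (length(unknown)) {
    stop("tissueGrouping: unknown tissue label(s): ",
         paste(unknown, collapse = ", "),
         ". Allowed: ", paste(c(colonTissues, ileumTissues), collapse = ", "))
  }
  ifelse(tissue %in% colonTissues, "colon_group", "ileum_group")
}

#' Maximum-score normalization table for histopathology scoring systems
#'
#' Maximum attainable scores of the modified Naini Cortina (Crohn's disease)
#' and modified Riley (ulcerative colitis) systems, by tissue group and
#' sampling method. These denominators put both systems on a common 0-1
#' scale.
#'
#' @return data.frame with columns system, tissue_group, method, max_score
#'   covering the full 2 x 2 x 2 grid.
#' @examples
#' defaultNormTable()
#' @export
defaultNormTable <- function() {
  data.frame(
    system = rep(c("NainiCortina", "Riley"), each = 4),
    tissue_group = rep(rep(c("colon_group", "ileum_group"), each = 2), 2),
    method = rep(c("resection", "biopsy"), 4),
    max_score = c(20L, 16L, 14L, 10L,   # modified Naini Cortina
                  21L, 17L, 16L, 12L),  # modified Riley
    stringsAsFactors = FALSE
  )
}

#' Look up the maximum histopathology score for a scoring context
#'
#' @param system \code{"NainiCortina"} or \code{"Riley"} (vectorized).
#' @param tissue_group \code{"colon_group"} or \code{"ileum_group"}.
#' @param method \code{"biopsy"} or \code{"resection"}.
#' @param table normalization table (default \code{\link{defaultNormTable}}).
#' @return integer vector of tabulated maxima.
#' @examples
#' maxScore("NainiCortina", "colon_group", "resection")  # 20
#' maxScore("Riley", "ileum_group", "biopsy")            # 12
#' @export
maxScore <- function(system, tissue_group, method, table = defaultNormTable()) {
  key <- paste(system, tissue_group, method, sep = "|")
  tabKey <- paste(table$system, table$tissue_group, table$method, sep = "|")
  idx <- match(key, tabKey)
  if (anyNA(idx)) {
    stop("maxScore: no tabulated maximum for: ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  table$max_score[idx]
}

#' Normalize raw histopathology scores to the 0-1 scale
#'
#' Divides each raw score by the maximum attainable score of its (system,
#' tissue group, sampling method) context, making modified Naini Cortina and
#' modified Riley scores directly comparable. Raw scores outside
#' [0, max] are rejected (they signal upstream scoring errors), never clipped.
#'
#' @param raw non-negative integer raw score(s).
#' @param system,tissue_group,method scoring context (vectorized).
#' @param table normalization table.
#' @return numeric normalized score(s) in [0, 1].
#' @examples
#' normalizeHisto(21, "Riley", "colon_group", "resection")      # 1
#' normalizeHisto(8, "NainiCortina", "ileum_group", "biopsy")   # 0.8
#' @export
normalizeHisto <- function(raw, system, tissue_group, method,
                           table = defaultNormTable()) {
  mx <- maxScore(system, tissue_group, method, table)
  if (any(raw < 0)) stop("normalizeHisto: negative raw score")
  if (any(raw > mx)) {
    bad <- which(raw > mx)[1]
    stop("normalizeHisto: raw score ", raw[bad], " exceeds maximum ",
         mx[bad], " for ", system[min(bad, length(system))], "/",
         tissue_group[min(bad, length(tissue_group))])
  }
  raw / mx
}

#' Label samples as inflamed / non-inflamed by tissue- and date-matched
#' histopathology
#'
#' A sample is \code{inflamed} if any histopathology record of the same
#' patient, in the same tissue group, within \code{window_days} of the sample
#' date has raw score > 0; \code{non_inflamed} if matching records exist and
#' all have raw score 0; \code{unknown} when no record matches. The default
#' window of 0 days demands exact date agreement (same-visit specimens).
#'
#' @param samples data.frame with columns patient_id, tissue_group, date.
#' @param histo data.frame of histopathology records with columns patient_id,
#'   tissue_group, date, raw.
#' @param window_days maximum |date difference| in days (default 0).
#' @return character vector over \code{inflamed}, \code{non_inflamed},
#'   \code{unknown}, one per sample row.
#' @export
inflammationStatus <- function(samples, histo, window_days = 0) {
  vapply(seq_len(nrow(samples)), function(i) {
    hit <- histo$patient_id == samples$patient_id[i] &
      histo$tissue_group == samples$tissue_group[i] &
      abs(as.numeric(as.Date(histo$date) - as.Date(samples$date[i]))) <= window_days
    if (!any(hit)) return("unknown")
    if (any(histo$raw[hit] > 0)) "inflamed" else "non_inflamed"
  }, character(1))
}

#' Assemble the tabular cohort bundle into a validated atlas store
#'
#' Reads (or accepts) the bundle tables, checks referential integrity
#' (orphan sample/patient ids, duplicate primary keys) and domain constraints
#' (histopathology raw scores within the tabulated maxima), and returns a
#' joined store together with an itemized violation report carrying row
#' provenance.
#'
#' @param bundle either a directory containing the bundle TSVs
#'   (patients.tsv, samples.tsv, histo.tsv, clinical.tsv, npx.tsv) or a named
#'   list of the corresponding data.frames.
#' @param normTable normalization table for score-range checks.
#' @param strict error (instead of warn) when violations are found.
#' @return list of class \code{"ibdAtlas"}: the tables plus a
#'   \code{violations} data.frame (table, row, rule, message).
#' @export
assembleAtlas <- function(bundle, normTable = defaultNormTable(),
                          strict = FALSE) {
  tabs <- if (is.character(bundle)) readCohortBundle(bundle) else bundle
  required <- c("patients", "samples", "histo")
  missing <- setdiff(required, names(tabs))
  if (length(missing))
    stop("assembleAtlas: bundle lacks table(s): ", paste(missing, collapse = ", "))

  viol <- list()
  addViol <- function(tab, rows, rule, msg) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(
        table = tab, row = rows, rule = rule, message = msg,
        stringsAsFactors = FALSE)
  }

  pat <- tabs$patients
  addViol("patients", which(duplicated(pat$patient_id)), "duplicate_key",
          "duplicated patient_id")
  smp <- tabs$samples
  addViol("samples", which(duplicated(smp$sample_id)), "duplicate_key",
          "duplicated sample_id")
  addViol("samples", which(!smp$patient_id %in% pat$patient_id),
          "orphan", "sample references unknown patient_id")
  his <- tabs$histo
  if (nrow(his)) {
    addViol("histo", which(!his$patient_id %in% pat$patient_id),
            "orphan", "histo record references unknown patient_id")
    key <- paste(his$system, his$tissue_group, his$method, sep = "|")
    tabKey <- paste(normTable$system, normTable$tissue_group, normTable$method,
                    sep = "|")
    mx <- normTable$max_score[match(key, tabKey)]
    addViol("histo", which(!is.na(mx) & (his$raw > mx | his$raw < 0)),
            "out_of_range", "raw histopathology score outside [0, max]")
    addViol("histo", which(is.na(mx)), "unknown_context",
            "no tabulated maximum for scoring context")
  }
  for (tab in intersect(c("clinical", "npx"), names(tabs))) {
    idcol <- if ("sample_id" %in% names(tabs[[tab]])) "sample_id" else NULL
    if ("patient_id" %in% names(tabs[[tab]]))
      addViol(tab, which(!tabs[[tab]]$patient_id %in% pat$patient_id),
              "orphan", "record references unknown patient_id")
    if (!is.null(idcol) && "sample_id" %in% names(smp))
      addViol(tab, which(!tabs[[tab]][[idcol]] %in% smp$sample_id),
              "orphan", "record references unknown sample_id")
  }

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(table = character(), row = integer(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  if (nrow(violations)) {
    msg <- sprintf("assembleAtlas: %d integrity violation(s)", nrow(violations))
    if (strict) stop(msg) else warning(msg)
  }
  structure(c(tabs, list(violations = violations)), class = "ibdAtlas")
}

#' @export
print.ibdAtlas <- function(x, ...) {
  tabs <- setdiff(names(x), "violations")
  cat("ibdAtlas store with tables:",
      paste(sprintf("%s(%d)", tabs, vapply(x[tabs], nrow, 1L)), collapse = ", "),
      "\n")
  cat("  violations:", nrow(x$violations), "\n")
  invisible(x)
}

#' Write / read the tabular cohort bundle
#'
#' TSV round-trip for the atlas tables; \code{exportAtlas} reproduces the
#' bundle row-set that \code{assembleAtlas} consumed.
#'
#' @param tabs named list of data.frames.
#' @param dir target / source directory.
#' @return \code{readCohortBundle}: named list of data.frames.
#' @export
writeCohortBundle <- function(tabs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tabs)) {
    if (is.data.frame(tabs[[nm]]))
      utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeCohortBundle
#' @export
readCohortBundle <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tabs <- lapply(files, utils::read.delim, sep = "\t", stringsAsFactors = FALSE,
                 check.names = FALSE)
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  tabs
}

#' @rdname writeCohortBundle
#' @param atlas an assembled atlas store.
#' @export
exportAtlas <- function(atlas, dir) {
  writeCohortBundle(atlas[setdiff(names(atlas), "violations")], dir)
}
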