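#' @importFrom utils read.delim write.table head tail
NULL

## Closed vocabularies ------------------------------------------------------

#' Family and subfamily vocabularies
#'
#' Communication molecules are classified into six named families; anything
#' else (hormones, adhesion molecules, ...) is grouped as \code{"other"}.
#' Cytokines are further classified into seven structural subfamilies, plus
#' \code{"unclassified"} for cytokines that fit none.
#'
#' @return Character vector of valid labels.
#' @export
lr_families <- function() {
  c("Growth factor", "Cytokine", "Chemokine", "Checkpoint",
    "Notch signaling", "Antigen binding", "other")
}

#' @rdname lr_families
#' @export
cytokine_subfamilies <- function() {
  c("type 1", "type 2", "IL-1 family", "IL-17 family",
    "TNF family", "TGF family", "RTK", "unclassified")
}

## Column mapping ------------------------------------------------------------

#' Default column mapping for ligand-receptor database files
#'
#' Maps file column names to their roles. The shipped database uses the
#' conventional layout: two ligand subunit columns, two receptor subunit
#' columns, then family, subfamily and PubMed ID.
#'
#' @param ligand character vector of ligand-subunit column names (1-2).
#' @param receptor character vector of receptor-subunit column names (1-2).
#' @param family,subfamily,pmid single column names (subfamily and pmid may
#'   be \code{NA} if absent from the file).
#' @return A named list usable as the \code{mapping} argument of
#'   \code{\link{load_lr_database}}.
#' @export
db_column_mapping <- function(ligand = c("Ligand.1", "Ligand.2"),
                              receptor = c("Receptor.1", "Receptor.2"),
                              family = "Family",
                              subfamily = "Subfamily",
                              pmid = "PubMed.ID") {
  stopifnot(length(ligand) >= 1, length(receptor) >= 1)
  list(ligand = ligand, receptor = receptor, family = family,
       subfamily = subfamily, pmid = pmid)
}

#' Path to the shipped synthetic ligand-receptor database
#'
#' The curated database distributed with the original framework is
#' supplementary material that cannot be redistributed here; this package
#' ships a synthetic stand-in with the same schema and the same published
#' counts (380 interactions, 194 cytokine interactions across 7 subfamilies,
#' 6 named families plus "other"). Paper-highlighted pairs (CD86/CD28,
#' CCL22/CCR4, PDCD1LG2/PDCD1, JAG1/NOTCH1, ...) appear verbatim; remaining
#' rows use synthetic gene symbols.
#'
#' @return File path of the TSV inside the installed package.
#' @export
lr_database_path <- function() {
  system.file("extdata", "lr_database_synthetic.tsv",
              package = "commscore", mustWork = TRUE)
}

## Constructor ---------------------------------------------------------------

new_lr_database <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("interaction_id", "ligand_1", "ligand_2",
              "receptor_1", "receptor_2", "family", "subfamily", "pmid")
  stopifnot(all(needed %in% names(records)))
  structure(records, class = c("lr_database", "data.frame"))
}

#' Construct a ligand-receptor database from vectors
#'
#' Low-level constructor used by the loader, the synthetic generator and
#' tests. Subunit slots that are absent must be \code{NA}.
#'
#' @param ligand_1,receptor_1 mandatory first subunits (gene symbols).
#' @param ligand_2,receptor_2 optional second subunits (\code{NA} if absent).
#' @param family family labels (normalized to the closed vocabulary).
#' @param subfamily optional subfamily labels.
#' @param pmid optional PubMed id strings (";"-separated for several).
#' @param validate if TRUE (default) hard invariants are enforced.
#' @return An \code{lr_database} (a data.frame subclass).
#' @export
lr_database <- function(ligand_1, receptor_1,
                        ligand_2 = NA_character_, receptor_2 = NA_character_,
                        family = "other", subfamily = NA_character_,
                        pmid = NA_character_, validate = TRUE) {
  n <- length(ligand_1)
  rec <- data.frame(
    interaction_id = paste(
      ifelse(is.na(ligand_2), ligand_1, paste(ligand_1, ligand_2, sep = "+")),
      ifelse(is.na(rep_len(receptor_2, n)), receptor_1,
             paste(receptor_1, rep_len(receptor_2, n), sep = "+")),
      sep = " / "),
    ligand_1 = trimws(ligand_1),
    ligand_2 = trimws(rep_len(as.character(ligand_2), n)),
    receptor_1 = trimws(receptor_1),
    receptor_2 = trimws(rep_len(as.character(receptor_2), n)),
    family = normalize_family(rep_len(family, n)),
    subfamily = normalize_subfamily(rep_len(as.character(subfamily), n)),
    pmid = rep_len(as.character(pmid), n),
    stringsAsFactors = FALSE
  )
  db <- new_lr_database(rec)
  if (validate) {
    rep_ <- validate_lr_database(db)
    bad <- rep_$findings[rep_$findings$severity == "error", , drop = FALSE]
    if (nrow(bad) > 0)
      stop("invalid ligand-receptor records: ",
           paste(unique(bad$message), collapse = "; "))
  }
  db
}

normalize_family <- function(x) {
  x <- trimws(as.character(x))
  vocab <- lr_families()
  idx <- match(tolower(x), tolower(vocab))
  out <- vocab[idx]
  out[is.na(idx) & !is.na(x) & nzchar(x)] <- NA_character_ # flagged by validator
  out[is.na(x) | !nzchar(x)] <- "other"
  # keep original text for unmatched so the validator can report it
  unmatched <- is.na(idx) & !is.na(x) & nzchar(x)
  out[unmatched] <- x[unmatched]
  out
}

normalize_subfamily <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  vocab <- cytokine_subfamilies()
  idx <- match(tolower(x), tolower(vocab))
  out <- ifelse(is.na(idx), x, vocab[idx])
  out
}

## Accessors -----------------------------------------------------------------

#' Set of all gene symbols appearing in a database
#' @param db an \code{lr_database}.
#' @return Character vector (sorted, unique).
#' @export
gene_universe <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  g <- c(db$ligand_1, db$ligand_2, db$receptor_1, db$receptor_2)
  sort(unique(g[!is.na(g) & nzchar(g)]))
}

ligand_subunits <- function(db, i) {
  g <- c(db$ligand_1[i], db$ligand_2[i])
  g[!is.na(g) & nzchar(g)]
}

receptor_subunits <- function(db, i) {
  g <- c(db$receptor_1[i], db$receptor_2[i])
  g[!is.na(g) & nzchar(g)]
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("ligand-receptor database: %d interactions, %d genes\n",
              nrow(x), length(gene_universe(x))))
  tab <- table(factor(x$family, levels = lr_families()))
  cat(paste(sprintf("  %-16s %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

## Loading -------------------------------------------------------------------

#' Load a ligand-receptor interaction database from delimited text
#'
#' Reads a tab- or comma-delimited file whose columns are mapped to roles by
#' \code{mapping}. One record per row; blank subunit cells mean absent
#' subunits; family and subfamily are matched case-insensitively against the
#' closed vocabularies. Rows that cannot be turned into a valid record
#' (empty ligand or receptor side) are collected in the attached validation
#' report, not silently dropped.
#'
#' @param path file path.
#' @param mapping a \code{\link{db_column_mapping}}.
#' @param sep field separator; guessed from the first line when NULL.
#' @return An \code{lr_database}; attribute \code{"report"} carries the
#'   load-time validation report (see \code{\link{validate_lr_database}}).
#' @examples
#' db <- load_lr_database(lr_database_path())
#' nrow(db)
#' @export
load_lr_database <- function(path, mapping = db_column_mapping(), sep = NULL) {
  if (!file.exists(path)) stop("database file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  want <- function(cols) cols[!is.na(cols)]
  lig_cols <- want(mapping$ligand)
  rec_cols <- want(mapping$receptor)
  missing_cols <- setdiff(c(lig_cols[1], rec_cols[1]), names(raw))
  if (length(missing_cols) > 0)
    stop("database file lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  getcol <- function(nm, default = NA_character_) {
    if (!is.na(nm) && nm %in% names(raw)) as.character(raw[[nm]])
    else rep(default, nrow(raw))
  }
  db <- lr_database(
    ligand_1   = getcol(lig_cols[1]),
    ligand_2   = if (length(lig_cols) > 1) getcol(lig_cols[2]) else NA,
    receptor_1 = getcol(rec_cols[1]),
    receptor_2 = if (length(rec_cols) > 1) getcol(rec_cols[2]) else NA,
    family     = getcol(mapping$family, "other"),
    subfamily  = getcol(mapping$subfamily),
    pmid       = getcol(mapping$pmid),
    validate = FALSE
  )
  report <- validate_lr_database(db)
  bad_side <- report$findings[report$findings$type == "empty_side", , drop = FALSE]
  if (nrow(bad_side) > 0) {
    db <- new_lr_database(db[-bad_side$row, , drop = FALSE])
    rownames(db) <- NULL
    warning(sprintf("%d row(s) with an empty ligand or receptor side removed; see attached report",
                    nrow(bad_side)))
  }
  # out-of-vocabulary families were recorded above; group them as "other"
  db$family[!db$family %in% lr_families()] <- "other"
  attr(db, "report") <- report
  db
}

#' Write a database back to delimited text
#'
#' Round-trips with \code{\link{load_lr_database}} record-for-record.
#'
#' @param db an \code{lr_database}.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_lr_database <- function(db, path, sep = "\t") {
  stopifnot(inherits(db, "lr_database"))
  out <- data.frame(
    `Ligand 1` = db$ligand_1, `Ligand 2` = db$ligand_2,
    `Receptor 1` = db$receptor_1, `Receptor 2` = db$receptor_2,
    Family = db$family, Subfamily = db$subfamily, `PubMed ID` = db$pmid,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

## Filtering -----------------------------------------------------------------

#' Filter a database by family, subfamily and/or gene set
#'
#' Records must match every provided filter. The gene filter keeps a record
#' only if every subunit on both sides is in \code{genes}. With no filters
#' the database is returned unchanged.
#'
#' @param db an \code{lr_database}.
#' @param families,subfamilies,genes optional character vectors.
#' @return The filtered \code{lr_database}.
#' @examples
#' db <- load_lr_database(lr_database_path())
#' nrow(filter_lr_database(db, families = "Cytokine"))
#' @export
filter_lr_database <- function(db, families = NULL, subfamilies = NULL,
                               genes = NULL) {
  stopifnot(inherits(db, "lr_database"))
  keep <- rep(TRUE, nrow(db))
  if (!is.null(families)) {
    bad <- setdiff(families, lr_families())
    if (length(bad) > 0)
      stop("unknown family name(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(lr_families(), collapse = ", "))
    keep <- keep & db$family %in% families
  }
  if (!is.null(subfamilies))
    keep <- keep & !is.na(db$subfamily) & db$subfamily %in% subfamilies
  if (!is.null(genes)) {
    genes <- trimws(genes)
    ok <- vapply(seq_len(nrow(db)), function(i) {
      all(c(ligand_subunits(db, i), receptor_subunits(db, i)) %in% genes)
    }, logical(1))
    keep <- keep & ok
  }
  out <- new_lr_database(db[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

## Validation ----------------------------------------------------------------

#' Validate a ligand-receptor database
#'
#' Report-only: lists duplicate (ligand set, receptor set) pairs, rows with
#' an empty ligand or receptor side, duplicated symbols within one side,
#' out-of-vocabulary families (with the suggestion "other") and malformed
#' PubMed ids. The database itself is never modified.
#'
#' @param db an \code{lr_database}.
#' @return A list of class \code{lr_validation} with elements
#'   \code{n_records}, \code{findings} (data.frame: row, type, severity,
#'   message) and \code{ok} (TRUE when no findings).
#' @export
validate_lr_database <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  f <- list()
  add <- function(row, type, severity, message) {
    f[[length(f) + 1]] <<- data.frame(row = row, type = type,
                                      severity = severity, message = message,
                                      stringsAsFactors = FALSE)
  }
  n <- nrow(db)
  pair_key <- character(n)
  for (i in seq_len(n)) {
    lig <- ligand_subunits(db, i)
    rec <- receptor_subunits(db, i)
    if (length(lig) == 0)
      add(i, "empty_side", "error", "empty ligand side")
    if (length(rec) == 0)
      add(i, "empty_side", "error", "empty receptor side")
    if (anyDuplicated(lig) || anyDuplicated(rec))
      add(i, "dup_subunit", "error", "duplicated subunit symbol within one side")
    pair_key[i] <- paste(paste(sort(lig), collapse = "+"),
                         paste(sort(rec), collapse = "+"), sep = "|")
  }
  dup <- which(duplicated(pair_key) & nzchar(gsub("\\|", "", pair_key)))
  for (i in dup)
    add(i, "duplicate_pair", "warning",
        sprintf("duplicate ligand/receptor pair: %s", db$interaction_id[i]))
  oov <- which(!db$family %in% lr_families())
  for (i in oov)
    add(i, "family_vocabulary", "warning",
        sprintf("family '%s' not in vocabulary; suggestion: 'other'",
                db$family[i]))
  oov_sub <- which(!is.na(db$subfamily) &
                     !db$subfamily %in% cytokine_subfamilies())
  for (i in oov_sub)
    add(i, "subfamily_vocabulary", "warning",
        sprintf("subfamily '%s' not in vocabulary", db$subfamily[i]))
  pm <- db$pmid
  badpm <- which(!is.na(pm) & nzchar(pm) &
                   !grepl("^[0-9]{1,8}([;,][ ]?[0-9]{1,8})*$", pm))
  for (i in badpm)
    add(i, "pmid_format", "warning",
        sprintf("malformed PubMed id '%s'", pm[i]))
  findings <- if (length(f) > 0) do.call(rbind, f) else
    data.frame(row = integer(0), type = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  structure(list(n_records = n, findings = findings,
                 ok = nrow(findings) == 0),
            class = "lr_validation")
}

#' @export
print.lr_validation <- function(x, ...) {
  cat(sprintf("validation of %d records: %s\n", x$n_records,
              if (x$ok) "no findings" else
                sprintf("%d finding(s)", nrow(x$findings))))
  if (!x$ok) print(x$findings)
  invisible(x)
}

#' Drop duplicated ligand/receptor pairs, keeping the first occurrence
#'
#' Scoring sums over interactions, so duplicated pairs would silently
#' inflate the global score; callers should deduplicate before scoring.
#'
#' @param db an \code{lr_database}.
#' @return Deduplicated \code{lr_database}.
#' @export
dedupe_lr_database <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  n <- nrow(db)
  key <- vapply(seq_len(n), function(i)
    paste(paste(sort(ligand_subunits(db, i)), collapse = "+"),
          paste(sort(receptor_subunits(db, i)), collapse = "+"), sep = "|"),
    character(1))
  out <- new_lr_database(db[!duplicated(key), , drop = FALSE])
  rownames(out) <- NULL
  out
}
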