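#' Trim a raw sequence to the barcode region between two primer anchors
#'
#' Locates the forward and reverse anchor sequences (allowing up to
#' `max_mismatch` substitutions each, found by a brute-force Hamming scan) and
#' returns the uppercased inter-anchor region. Characters outside A/C/G/T/N
#' cause an error.
#'
#' @param raw_seq raw nucleotide sequence (character scalar).
#' @param anchor_primers character vector of length 2: forward and reverse
#'   anchor sequences, both in the orientation of `raw_seq`.
#' @param max_mismatch maximum substitutions tolerated per anchor (default 2).
#' @return the inter-anchor region, or an error of class `untrimmable_error`
#'   when either anchor cannot be located.
#' @export
trim_to_region <- function(raw_seq, anchor_primers, max_mismatch = 2L) {
  stopifnot(length(anchor_primers) == 2L, nchar(raw_seq) > 0L)
  raw <- toupper(raw_seq)
  fwd <- toupper(anchor_primers[1]); rev <- toupper(anchor_primers[2])
  f <- find_anchor(raw, fwd, max_mismatch)
  if (is.na(f))
    stop(untrimmable_error("forward anchor not found"))
  rstart_min <- f + nchar(fwd)
  r <- find_anchor(raw, rev, max_mismatch, from = rstart_min)
  if (is.na(r))
    stop(untrimmable_error("reverse anchor not found"))
  region <- substr(raw, rstart_min, r - 1L)
  if (!grepl("^[ACGTN]*$", region))
    stop(untrimmable_error("non-ACGTN characters in trimmed region"))
  region
}

untrimmable_error <- function(msg) {
  structure(class = c("untrimmable_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# First position (1-based) where `anchor` matches `seq` with <= mm mismatches.
find_anchor <- function(seq, anchor, mm, from = 1L) {
  n <- nchar(seq); k <- nchar(anchor)
  if (k == 0L || from + k - 1L > n) return(NA_integer_)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- strsplit(anchor, "", fixed = TRUE)[[1]]
  for (i in from:(n - k + 1L)) {
    if (sum(s[i:(i + k - 1L)] != a) <= mm) return(i)
  }
  NA_integer_
}

#' Build a curated barcode reference database
#'
#' Deduplicates trimmed region sequences into unique entries with merged
#' source-species sets and accession labels, drops blacklisted accessions,
#' classifies each entry's taxonomic resolution against the flora, and reports
#' flora species with no usable sequence.
#'
#' @param flora data.frame with columns species, genus, family, growth_form,
#'   in_area, is_bait (one row per species; one family per genus).
#' @param pool data.frame with columns accession, species, sequence and
#'   optionally tier (`local_survey`/`external_pool`, default external), or
#'   the path to a FASTA file with headers `accession|species[|tier]`.
#' @param blacklist optional data.frame (accession, reason) or TSV path:
#'   accessions excluded from the build (e.g. misidentified submissions).
#' @param anchor_primers optional primer pair passed to [trim_to_region()];
#'   when `NULL`, pool sequences are taken as already trimmed.
#' @param region_length expected trimmed length; entries of any other length
#'   are rejected as untrimmable. `NULL` skips the check.
#' @return object of class `ref_db`: list with `entries` (data.frame:
#'   sequence, species (";"-joined), tier, resolution, accessions), `uncovered`
#'   (flora species with no entry), `blacklisted`, `untrimmable`, and
#'   `bait_confounded` (filled by [flag_bait_confounded()]).
#' @export
build_database <- function(flora, pool, blacklist = NULL,
                           anchor_primers = NULL, region_length = NULL) {
  validate_flora(flora)
  if (is.character(pool) && length(pool) == 1L) pool <- read_pool_fasta(pool)
  stopifnot(all(c("accession", "species", "sequence") %in% names(pool)))
  if (is.null(pool$tier)) pool$tier <- "external_pool"
  if (is.character(blacklist) && length(blacklist) == 1L)
    blacklist <- utils::read.delim(blacklist, stringsAsFactors = FALSE)
  offenders <- setdiff(pool$species, flora$species)
  if (length(offenders))
    stop("pool species absent from flora: ",
         paste(sort(offenders), collapse = ", "), call. = FALSE)
  dropped <- data.frame(accession = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(blacklist) && nrow(blacklist)) {
    hit <- pool$accession %in% blacklist$accession
    dropped <- data.frame(
      accession = pool$accession[hit],
      reason = blacklist$reason[match(pool$accession[hit],
                                      blacklist$accession)] %||% "blacklisted",
      stringsAsFactors = FALSE)
    pool <- pool[!hit, , drop = FALSE]
  }
  untrimmable <- data.frame(accession = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  seqs <- toupper(pool$sequence)
  if (!is.null(anchor_primers)) {
    trimmed <- character(nrow(pool)); ok <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      res <- tryCatch(trim_to_region(seqs[i], anchor_primers),
                      untrimmable_error = function(e) e)
      if (inherits(res, "untrimmable_error")) {
        untrimmable <- rbind(untrimmable, data.frame(
          accession = pool$accession[i], reason = conditionMessage(res),
          stringsAsFactors = FALSE))
      } else {
        trimmed[i] <- res; ok[i] <- TRUE
      }
    }
    pool <- pool[ok, , drop = FALSE]; seqs <- trimmed[ok]
  }
  if (!is.null(region_length)) {
    bad <- nchar(seqs) != region_length
    if (any(bad)) {
      untrimmable <- rbind(untrimmable, data.frame(
        accession = pool$accession[bad], reason = "wrong region length",
        stringsAsFactors = FALSE))
      pool <- pool[!bad, , drop = FALSE]; seqs <- seqs[!bad]
    }
  }
  # deduplicate into unique entries, stable order by sequence
  uniq <- sort(unique(seqs))
  entries <- do.call(rbind, lapply(uniq, function(sq) {
    idx <- which(seqs == sq)
    sp <- sort(unique(pool$species[idx]))
    data.frame(
      sequence = sq,
      species = paste(sp, collapse = ";"),
      tier = if (any(pool$tier[idx] == "local_survey")) "local_survey"
             else "external_pool",
      accessions = paste(sort(pool$accession[idx]), collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  if (is.null(entries))
    entries <- data.frame(sequence = character(0), species = character(0),
                          tier = character(0), accessions = character(0),
                          stringsAsFactors = FALSE)
  entries$resolution <- vapply(entries$species, function(sp)
    resolution_class(strsplit(sp, ";", fixed = TRUE)[[1]], flora), "")
  rownames(entries) <- NULL
  covered <- unique(unlist(strsplit(entries$species, ";", fixed = TRUE)))
  db <- structure(list(
    entries = entries,
    uncovered = sort(setdiff(flora$species, covered)),
    blacklisted = dropped,
    untrimmable = untrimmable,
    bait_confounded = data.frame(species = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE),
    flora = flora
  ), class = "ref_db")
  db
}

validate_flora <- function(flora) {
  need <- c("species", "genus", "family", "growth_form", "in_area", "is_bait")
  stopifnot(is.data.frame(flora), all(need %in% names(flora)))
  if (anyDuplicated(flora$species))
    stop("flora species names must be unique", call. = FALSE)
  fam_per_genus <- tapply(flora$family, flora$genus,
                          function(x) length(unique(x)))
  if (any(fam_per_genus > 1L))
    stop("each genus must belong to a single family", call. = FALSE)
  invisible(flora)
}

read_pool_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(
    accession = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L),
    tier = vapply(parts, function(p) if (length(p) >= 3L) p[3L]
                  else "external_pool", ""),
    sequence = as.character(x),
    stringsAsFactors = FALSE)
}

# Resolution class of one unique sequence given its source-species set.
resolution_class <- function(species_set, flora) {
  i <- match(species_set, flora$species)
  if (anyNA(i)) stop("species not in flora: ",
                     paste(species_set[is.na(i)], collapse = ", "),
                     call. = FALSE)
  if (length(species_set) == 1L) return("species_specific")
  if (length(unique(flora$genus[i])) == 1L) return("genus_shared")
  if (length(unique(flora$family[i])) == 1L) return("family_shared")
  "unassignable"
}

#' Summarize taxonomic resolution of a reference database
#'
#' Counts unique entries per resolution class (species-specific, shared within
#' a genus, shared within a family, unassignable) with percentages over the
#' unique-entry count, reported to one decimal.
#'
#' @param db a `ref_db`.
#' @return data.frame with columns class, count, percent.
#' @export
classify_resolution <- function(db) {
  stopifnot(inherits(db, "ref_db"))
  classes <- c("species_specific", "genus_shared", "family_shared",
               "unassignable")
  counts <- vapply(classes, function(cl) sum(db$entries$resolution == cl),
                   numeric(1))
  data.frame(class = classes, count = as.integer(counts),
             percent = pct1(100 * counts / max(1L, nrow(db$entries))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag species confounded with trap bait
#'
#' An in-area species every one of whose unique sequences is also carried by a
#' bait species cannot be told apart from the bait, and is excluded together
#' with the bait species themselves. A species retaining at least one
#' bait-free sequence stays in. The exclusions are recorded on the returned
#' database with reason "bait-confounded".
#'
#' @param db a `ref_db` built over a flora that flags bait species.
#' @return the database with `bait_confounded` filled in.
#' @export
flag_bait_confounded <- function(db) {
  stopifnot(inherits(db, "ref_db"))
  flora <- db$flora
  bait <- flora$species[flora$is_bait]
  sets <- strsplit(db$entries$species, ";", fixed = TRUE)
  excluded <- character(0)
  if (length(bait)) {
    in_area <- flora$species[flora$in_area & !flora$is_bait]
    for (sp in in_area) {
      carrying <- vapply(sets, function(s) sp %in% s, logical(1))
      if (!any(carrying)) next
      if (all(vapply(sets[carrying], function(s) any(bait %in% s),
                     logical(1))))
        excluded <- c(excluded, sp)
    }
    excluded <- c(excluded, bait[vapply(bait, function(b)
      any(vapply(sets, function(s) b %in% s, logical(1))), logical(1))])
  }
  db$bait_confounded <- data.frame(
    species = sort(unique(excluded)),
    reason = if (length(excluded)) "bait-confounded" else character(0),
    stringsAsFactors = FALSE)
  db
}

#' @export
print.ref_db <- function(x, ...) {
  cat("Barcode reference database\n")
  cat(sprintf("  unique entries : %d\n", nrow(x$entries)))
  cat(sprintf("  covered species: %d (uncovered: %d)\n",
              length(unique(unlist(strsplit(x$entries$species, ";",
                                            fixed = TRUE)))),
              length(x$uncovered)))
  cat(sprintf("  blacklisted accessions: %d; untrimmable: %d\n",
              nrow(x$blacklisted), nrow(x$untrimmable)))
  if (nrow(x$bait_confounded))
    cat("  bait-confounded:", paste(x$bait_confounded$species,
                                    collapse = ", "), "\n")
  res <- classify_resolution(x)
  for (i in seq_len(nrow(res)))
    cat(sprintf("  %-17s %5d (%.1f%%)\n", res$class[i], res$count[i],
                res$percent[i]))
  invisible(x)
}

#' Write a reference database to TSV
#'
#' @param db a `ref_db`.
#' @param path output TSV path (columns sequence, species, tier, resolution,
#'   accessions).
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  utils::write.table(db$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
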