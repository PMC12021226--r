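#' Build the sample x taxon diet presence table
#'
#' A taxon is present in a sample iff at least one `assigned` ASV with at
#' least one read in that sample resolves to it. Distinct tie sets resolving
#' to the same family name become distinct taxa and receive numbered labels
#' ("Familyname-1", "Familyname-2", ...) ordered by decreasing overall
#' occurrence. Excluded and unassigned ASVs contribute nothing.
#'
#' @param assign an `asv_assignments` object (or its `assignments` frame).
#' @param tab the rarefied `asv_table` the assignments were computed from.
#' @param metadata data.frame with sample_id, season and/or collection_month;
#'   seasons are derived from months (Mar-May spring, Jun-Aug summer, Sep-Nov
#'   autumn, Dec-Feb winter) when absent.
#' @param flora flora data.frame (for family and growth form lookups).
#' @return object of class `diet_table`: list with `presence` (logical matrix
#'   samples x taxa), `taxa` (data.frame label, rank, name, family,
#'   growth_form, matched_species) and `samples` (data.frame sample_id,
#'   season).
#' @export
build_diet_table <- function(assign, tab, metadata, flora) {
  a <- if (inherits(assign, "asv_assignments")) assign$assignments else assign
  stopifnot(inherits(tab, "asv_table"))
  samples <- rownames(tab$counts)
  miss <- setdiff(samples, metadata$sample_id)
  if (length(miss))
    stop("samples lacking metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  season <- if (!is.null(md$season)) md$season
            else month_to_season(md$collection_month)
  if (!all(season %in% SEASONS))
    stop("sample lacking valid season metadata", call. = FALSE)
  ok <- a[a$status == "assigned", , drop = FALSE]
  # a taxon is one distinct (rank, name, tie set)
  key <- paste(ok$rank, ok$name, ok$matched_species, sep = "\r")
  ukeys <- unique(key)
  presence <- matrix(FALSE, nrow = length(samples), ncol = length(ukeys),
                     dimnames = list(samples, NULL))
  taxa <- data.frame(rank = character(length(ukeys)),
                     name = character(length(ukeys)),
                     family = character(length(ukeys)),
                     growth_form = character(length(ukeys)),
                     matched_species = character(length(ukeys)),
                     stringsAsFactors = FALSE)
  for (j in seq_along(ukeys)) {
    rows <- ok[key == ukeys[j], , drop = FALSE]
    ids <- rows$asv_id[rows$asv_id %in% colnames(tab$counts)]
    if (length(ids))
      presence[, j] <- rowSums(tab$counts[, ids, drop = FALSE]) > 0L
    sp <- strsplit(rows$matched_species[1], ";", fixed = TRUE)[[1]]
    fi <- match(sp, flora$species)
    taxa$rank[j] <- rows$rank[1]
    taxa$name[j] <- rows$name[1]
    taxa$family[j] <- unique(flora$family[fi])[1]
    gf <- flora$growth_form[fi]
    taxa$growth_form[j] <- names(sort(table(gf), decreasing = TRUE))[1]
    taxa$matched_species[j] <- rows$matched_species[1]
  }
  taxa$label <- taxon_labels(taxa, colSums(presence))
  ord <- order(taxa$family, taxa$label)
  taxa <- taxa[ord, , drop = FALSE]; rownames(taxa) <- NULL
  presence <- presence[, ord, drop = FALSE]
  colnames(presence) <- taxa$label
  structure(list(presence = presence, taxa = taxa,
                 samples = data.frame(sample_id = samples, season = season,
                                      stringsAsFactors = FALSE)),
            class = "diet_table")
}

month_to_season <- function(month) {
  out <- rep(NA_character_, length(month))
  for (s in SEASONS) out[month %in% SEASON_MONTHS[[s]]] <- s
  out
}

# Family-rank taxa sharing one family name get "-1", "-2" suffixes ordered by
# decreasing overall occurrence; all other taxa keep their resolved name.
taxon_labels <- function(taxa, overall) {
  label <- taxa$name
  for (nm in unique(taxa$name[taxa$rank == "family"])) {
    idx <- which(taxa$name == nm & taxa$rank == "family")
    if (length(idx) > 1L) {
      r <- rank(-overall[idx], ties.method = "first")
      label[idx] <- paste0(nm, "-", r)
    }
  }
  genus_idx <- taxa$rank == "genus"
  label[genus_idx] <- paste(taxa$name[genus_idx], "spp.")
  # genus taxa sharing a name (distinct tie sets) get numbered too
  for (nm in unique(label[genus_idx])) {
    idx <- which(label == nm & genus_idx)
    if (length(idx) > 1L) {
      r <- rank(-overall[idx], ties.method = "first")
      label[idx] <- paste0(nm, "-", r)
    }
  }
  make.unique(label, sep = "-")
}

#' Frequency of occurrence per taxon, per season and overall
#'
#' The number of samples in which each taxon was detected divided by the
#' number of samples, per season and overall, as one-decimal percentages.
#'
#' @param diet a `diet_table`.
#' @return data.frame, one row per taxon, sorted by decreasing overall
#'   occurrence: label, family, rank, growth_form, the four seasonal counts
#'   and percents, overall count and percent.
#' @export
frequency_of_occurrence <- function(diet) {
  stopifnot(inherits(diet, "diet_table"))
  if (!ncol(diet$presence)) stop("empty diet table", call. = FALSE)
  season <- diet$samples$season
  n_season <- vapply(SEASONS, function(s) sum(season == s), integer(1))
  n_all <- nrow(diet$presence)
  out <- data.frame(label = diet$taxa$label, family = diet$taxa$family,
                    rank = diet$taxa$rank,
                    growth_form = diet$taxa$growth_form,
                    stringsAsFactors = FALSE)
  for (s in SEASONS) {
    cnt <- colSums(diet$presence[season == s, , drop = FALSE])
    out[[s]] <- as.integer(cnt)
    out[[paste0(s, "_pct")]] <-
      if (n_season[[s]] > 0) pct1(100 * cnt / n_season[[s]]) else NA_real_
  }
  out$overall <- as.integer(colSums(diet$presence))
  out$overall_pct <- pct1(100 * out$overall / n_all)
  out <- out[order(-out$overall, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- c(stats::setNames(as.integer(n_season), SEASONS),
                              all = n_all)
  out
}

#' Taxonomic-resolution breakdown of identified taxa
#'
#' Counts taxa identified at species, genus and family level, with
#' percentages over the total number of taxa (one decimal).
#'
#' @param diet a `diet_table`, or a data.frame with a `rank` column (e.g. the
#'   packaged reference table).
#' @return data.frame with columns rank, count, percent.
#' @export
resolution_summary <- function(diet) {
  ranks <- if (inherits(diet, "diet_table")) diet$taxa$rank else diet$rank
  lev <- c("species", "genus", "family")
  counts <- vapply(lev, function(r) sum(ranks == r), integer(1))
  data.frame(rank = lev, count = as.integer(counts),
             percent = pct1(100 * counts / max(1L, length(ranks))),
             stringsAsFactors = FALSE)
}

#' Woody vs herbaceous breakdown of identified taxa
#'
#' @param diet a `diet_table`, or a data.frame with a `growth_form` column.
#' @return data.frame with columns growth_form and count.
#' @export
growth_form_summary <- function(diet) {
  gf <- if (inherits(diet, "diet_table")) diet$taxa$growth_form
        else diet$growth_form
  lev <- c("woody", "herbaceous")
  data.frame(growth_form = lev,
             count = vapply(lev, function(g) sum(gf == g), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of identified taxa per sample
#'
#' @param diet a `diet_table`.
#' @return list with `per_sample` (data.frame sample_id, season, n_taxa) and
#'   `stats` (data.frame per season plus "all": mean, median, min, max).
#' @export
taxa_per_sample <- function(diet) {
  stopifnot(inherits(diet, "diet_table"))
  n <- rowSums(diet$presence)
  per_sample <- data.frame(sample_id = diet$samples$sample_id,
                           season = diet$samples$season,
                           n_taxa = as.integer(n), stringsAsFactors = FALSE)
  grp <- c(as.list(split(n, factor(diet$samples$season, levels = SEASONS))),
           list(all = n))
  stats <- do.call(rbind, lapply(names(grp), function(g) {
    v <- grp[[g]]
    if (!length(v)) return(data.frame(group = g, mean = NA_real_,
                                      median = NA_real_, min = NA_real_,
                                      max = NA_real_))
    data.frame(group = g, mean = mean(v), median = stats::median(v),
               min = min(v), max = max(v))
  }))
  rownames(stats) <- NULL
  list(per_sample = per_sample, stats = stats)
}

#' Load the packaged reference diet table
#'
#' Reads the machine-readable transcription of the published diet table for
#' the field-mouse study (72 plant taxa in 43 families from 100 fecal
#' samples; seasonal sample sizes 22/35/32/11) and validates it on load:
#' exactly 72 rows, each row's overall count equal to the sum of its four
#' seasonal counts.
#'
#' @return data.frame with columns family, label, matched_species, rank,
#'   growth_form, database, the four seasonal counts and printed percents,
#'   overall count and printed percent; attribute `n_samples` holds the
#'   seasonal and total sample sizes.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "rbcldiet",
                      mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(tb) == 72L)
  season_cols <- SEASONS
  bad <- which(tb$overall != rowSums(tb[, season_cols]))
  if (length(bad))
    stop("reference table rows with inconsistent counts: ",
         paste(tb$label[bad], collapse = ", "), call. = FALSE)
  attr(tb, "n_samples") <- c(spring = 22L, summer = 35L, autumn = 32L,
                             winter = 11L, all = 100L)
  tb
}

#' @export
print.diet_table <- function(x, ...) {
  cat(sprintf("Diet table: %d samples x %d taxa (%d families)\n",
              nrow(x$presence), ncol(x$presence),
              length(unique(x$taxa$family))))
  print(utils::head(frequency_of_occurrence(x)[, c("label", "rank",
                                                   "overall",
                                                   "overall_pct")], 10),
        row.names = FALSE)
  invisible(x)
}
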