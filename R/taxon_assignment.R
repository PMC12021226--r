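#' Pipeline configuration
#'
#' Houses every numeric constant of the analysis: the 98% identity gate, the
#' 1,000-read rarefaction depth, the 1.0% per-sample low-frequency threshold,
#' 10,000 PerMANOVA permutations, 1,000 bootstrap replicates, 3 ordination
#' dimensions with a 0.2 stress ceiling, and alpha = 0.05.
#'
#' @param identity_gate minimum percent identity for an assignment (a hit at
#'   exactly the gate passes).
#' @param depth rarefaction depth (reads per sample).
#' @param lowfreq per-sample low-frequency threshold (fraction).
#' @param permutations PerMANOVA permutations.
#' @param bootstrap bootstrap replicates for diversity confidence intervals.
#' @param nmds_dims ordination dimensions.
#' @param stress_ceiling stress above which an ordination is considered
#'   unreliable.
#' @param alpha significance level.
#' @param seed integer seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(identity_gate = 98.0, depth = 1000L,
                            lowfreq = 0.01, permutations = 10000L,
                            bootstrap = 1000L, nmds_dims = 3L,
                            stress_ceiling = 0.2, alpha = 0.05, seed = 1L) {
  stopifnot(identity_gate > 0, identity_gate <= 100, depth >= 1,
            permutations >= 1, bootstrap >= 1, nmds_dims >= 1,
            alpha > 0, alpha < 1)
  structure(list(identity_gate = identity_gate, depth = as.integer(depth),
                 lowfreq = lowfreq, permutations = as.integer(permutations),
                 bootstrap = as.integer(bootstrap),
                 nmds_dims = as.integer(nmds_dims),
                 stress_ceiling = stress_ceiling, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Percent identity between two sequences under global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a linear
#' gap penalty of -2 per gap position, end gaps penalized; identity is the
#' number of matching columns divided by the total alignment columns, times
#' 100.
#'
#' @param query,reference non-empty nucleotide sequences.
#' @return percent identity in [0, 100].
#' @export
percent_identity <- function(query, reference) {
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  identity_from_alignment(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)))
}

identity_from_alignment <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  100 * sum(pc == sc & pc != "-") / length(pc)
}

# Identities of one query against every entry of a database (vectorized).
db_identities <- function(query, db) {
  seqs <- db$entries$sequence
  if (!length(seqs)) return(numeric(0))
  out <- numeric(length(seqs))
  exact <- seqs == query
  out[exact] <- 100
  todo <- which(!exact)
  if (length(todo)) {
    # equal-length, substitution-only comparisons reduce to Hamming under
    # this scoring whenever gaps cannot gain; run the full alignment anyway
    # for correctness, batched against the query.
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[todo]), Biostrings::DNAString(query),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 0, gapExtension = 2)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    out[todo] <- mapply(identity_from_alignment, pa, sa, USE.NAMES = FALSE)
  }
  out
}

#' Lowest common taxonomic rank of a species set
#'
#' Resolves a set of tied reference species to the most specific rank that
#' contains them all: one species -> species; one genus -> genus; one family
#' -> family; several families -> no assignment (rank `none`).
#'
#' @param species_set non-empty character vector of flora species names.
#' @param flora flora data.frame (species, genus, family, ...).
#' @return list(rank, name); rank `none` with name `NA` when the set spans
#'   multiple families.
#' @export
lowest_common_rank <- function(species_set, flora) {
  stopifnot(length(species_set) >= 1L)
  species_set <- unique(species_set)
  i <- match(species_set, flora$species)
  if (anyNA(i))
    stop("species not in taxonomy: ",
         paste(species_set[is.na(i)], collapse = ", "), call. = FALSE)
  if (length(species_set) == 1L)
    return(list(rank = "species", name = species_set))
  gen <- unique(flora$genus[i])
  if (length(gen) == 1L) return(list(rank = "genus", name = gen))
  fam <- unique(flora$family[i])
  if (length(fam) == 1L) return(list(rank = "family", name = fam))
  list(rank = "none", name = NA_character_)
}

#' Assign one ASV through the tiered identity search
#'
#' Implements the identification decision flow: search the local database
#' first; if the best identity passes the gate, resolve the exact-tie set
#' (entries within 1e-9 of the best identity) by lowest common rank over the
#' union of their source species. Otherwise fall back to the external
#' database, where assignments additionally pass ecological filters: species
#' flagged as bait (or bait-confounded in the local database) are discarded
#' (status `excluded_bait` when nothing remains), and out-of-area species not
#' on the planted allow-list are discarded (status `excluded_implausible`).
#' Below the gate on both tiers the ASV is `unassigned`.
#'
#' @param asv ASV sequence.
#' @param local_db curated local `ref_db`.
#' @param fallback_db external-pool `ref_db` (may be `NULL`).
#' @param flora flora data.frame.
#' @param cfg a [pipeline_config()].
#' @param allow_list species treated as plausible despite `in_area = FALSE`
#'   (planted ornamentals).
#' @return one-row data.frame: asv_id (NA here), tier, best_identity, rank,
#'   name, status, reason, matched_species.
#' @export
assign_asv <- function(asv, local_db, fallback_db, flora, cfg,
                       allow_list = character(0)) {
  gate <- cfg$identity_gate
  confounded <- local_db$bait_confounded$species
  res <- assignment_row(tier = "none", best_identity = NA_real_,
                        rank = NA_character_, name = NA_character_,
                        status = "unassigned", reason = "below gate on all tiers",
                        matched_species = "")
  for (tier in c("local", "fallback")) {
    db <- if (tier == "local") local_db else fallback_db
    if (is.null(db) || nrow(db$entries) == 0L) next
    ids <- db_identities(asv, db)
    best <- max(ids)
    if (tier == "local") res$best_identity <- best
    if (best < gate) next
    tie <- which(ids >= best - 1e-9)
    sp <- unique(unlist(strsplit(db$entries$species[tie], ";", fixed = TRUE)))
    res$tier <- tier
    res$best_identity <- best
    res$matched_species <- paste(sort(sp), collapse = ";")
    # bait and bait-confounded species are never food-plant evidence
    bait <- flora$species[flora$is_bait]
    keep <- setdiff(sp, c(bait, confounded))
    if (!length(keep)) {
      res$status <- "excluded_bait"
      res$reason <- "matches bait / bait-confounded taxa only"
      return(res)
    }
    if (tier == "fallback") {
      plausible <- keep[keep %in% c(flora$species[flora$in_area], allow_list)]
      if (!length(plausible)) {
        res$status <- "excluded_implausible"
        res$reason <- "matches out-of-area taxa only"
        return(res)
      }
      keep <- plausible
    }
    lca <- lowest_common_rank(keep, flora)
    if (lca$rank == "none") {
      res$status <- "unassigned"
      res$reason <- "tie spans multiple families"
      return(res)
    }
    res$status <- "assigned"
    res$rank <- lca$rank
    res$name <- lca$name
    res$reason <- ""
    return(res)
  }
  res
}

assignment_row <- function(tier, best_identity, rank, name, status, reason,
                           matched_species) {
  data.frame(asv_id = NA_character_, tier = tier,
             best_identity = best_identity, rank = rank, name = name,
             status = status, reason = reason,
             matched_species = matched_species, stringsAsFactors = FALSE)
}

#' Assign every ASV of a table and summarize identification outcomes
#'
#' @param tab an `asv_table` (normally the rarefied table).
#' @param local_db,fallback_db reference databases as in [assign_asv()].
#' @param flora flora data.frame.
#' @param cfg a [pipeline_config()].
#' @param allow_list planted-ornamental allow-list.
#' @return object of class `asv_assignments`: list with `assignments`
#'   (one row per ASV) and `summary` (counts and one-decimal percentages per
#'   tier and status, plus the local-tier pass percentage).
#' @export
assign_table <- function(tab, local_db, fallback_db, flora, cfg,
                         allow_list = character(0)) {
  stopifnot(inherits(tab, "asv_table"))
  rows <- lapply(names(tab$asv_seq), function(id) {
    r <- assign_asv(tab$asv_seq[[id]], local_db, fallback_db, flora, cfg,
                    allow_list)
    r$asv_id <- id
    r
  })
  assignments <- do.call(rbind, rows)
  n <- nrow(assignments)
  local_pass <- sum(assignments$tier == "local" &
                      assignments$best_identity >= cfg$identity_gate - 1e-9)
  status_counts <- table(factor(assignments$status,
                                levels = c("assigned", "excluded_bait",
                                           "excluded_implausible",
                                           "unassigned")))
  tier_counts <- table(factor(assignments$tier,
                              levels = c("local", "fallback", "none")))
  summary <- list(
    n_asvs = n,
    local_tier_count = as.integer(local_pass),
    local_tier_percent = pct1(100 * local_pass / max(1L, n)),
    by_status = data.frame(status = names(status_counts),
                           count = as.integer(status_counts),
                           percent = pct1(100 * as.integer(status_counts) /
                                            max(1L, n)),
                           stringsAsFactors = FALSE),
    by_tier = data.frame(tier = names(tier_counts),
                         count = as.integer(tier_counts),
                         percent = pct1(100 * as.integer(tier_counts) /
                                          max(1L, n)),
                         stringsAsFactors = FALSE)
  )
  structure(list(assignments = assignments, summary = summary),
            class = "asv_assignments")
}

#' @export
print.asv_assignments <- function(x, ...) {
  cat(sprintf("ASV assignments: %d ASVs; local tier %d (%.1f%%)\n",
              x$summary$n_asvs, x$summary$local_tier_count,
              x$summary$local_tier_percent))
  print(x$summary$by_status, row.names = FALSE)
  invisible(x)
}
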