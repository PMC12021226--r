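#' Simulation configuration for synthetic diet-metabarcoding data
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study conditions the package is validated under: a 262 bp plant barcode
#' region, 24 fecal samples spread over four seasons at 2,000 merged reads
#' each, a per-base substitution error rate of 1e-3, 2% chimeric reads, 5%
#' bait-derived reads and 1% out-of-area contaminant reads.
#'
#' @param n_families number of plant families in the toy flora.
#' @param genera_per_family genera per family.
#' @param species_per_genus species per genus.
#' @param region_length length (bp) of the barcode region; all simulated
#'   sequences have exactly this length.
#' @param within_genus_div Hamming distance (substitutions) between each
#'   non-reference species and its genus reference sequence. With 0, all
#'   congeners share one sequence, so genus-level ambiguity exists by
#'   construction.
#' @param within_family_div Hamming distance between each non-reference genus
#'   reference and its family reference sequence.
#' @param n_samples number of fecal samples.
#' @param season_assignment optional character vector (length `n_samples`) of
#'   seasons in `c("spring","summer","autumn","winter")`; default cycles
#'   through the four seasons.
#' @param diet_profile optional named list season -> named numeric vector of
#'   relative abundances over species names (each summing to 1). When `NULL`
#'   a default profile over the generated flora is constructed at sampling
#'   time: five core species shared by all seasons plus one season-specific
#'   species.
#' @param read_depth reads per sample.
#' @param error_rate per-base substitution probability applied i.i.d. to every
#'   emitted read.
#' @param chimera_rate expected fraction of reads that are two-parent chimeras.
#' @param bait_fraction expected fraction of reads copied from bait species.
#' @param contaminant_fraction expected fraction of reads copied from
#'   out-of-area contaminant species.
#' @param seed integer seed; the whole simulation is deterministic given it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 4L, genera_per_family = 3L,
                       species_per_genus = 3L, region_length = 262L,
                       within_genus_div = 13L, within_family_div = 30L,
                       n_samples = 24L, season_assignment = NULL,
                       diet_profile = NULL, read_depth = 2000L,
                       error_rate = 1e-3, chimera_rate = 0.02,
                       bait_fraction = 0.05, contaminant_fraction = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    region_length = as.integer(region_length),
    within_genus_div = as.integer(within_genus_div),
    within_family_div = as.integer(within_family_div),
    n_samples = as.integer(n_samples),
    season_assignment = season_assignment,
    diet_profile = diet_profile,
    read_depth = as.integer(read_depth),
    error_rate = error_rate,
    chimera_rate = chimera_rate,
    bait_fraction = bait_fraction,
    contaminant_fraction = contaminant_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

SEASONS <- c("spring", "summer", "autumn", "winter")
SEASON_MONTHS <- list(
  spring = 3:5, summer = 6:8, autumn = 9:11, winter = c(12L, 1L, 2L)
)

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_families >= 1L, cfg$genera_per_family >= 1L,
            cfg$species_per_genus >= 1L, cfg$n_samples >= 1L,
            cfg$read_depth >= 1L)
  if (cfg$region_length < 50L)
    stop("region_length must be at least 50 bases", call. = FALSE)
  fr <- c(cfg$chimera_rate, cfg$bait_fraction, cfg$contaminant_fraction,
          cfg$error_rate)
  if (any(fr < 0) || any(fr > 1))
    stop("all rates/fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$chimera_rate + cfg$bait_fraction + cfg$contaminant_fraction > 0.5)
    stop("chimera + bait + contaminant fractions must not exceed 0.5",
         call. = FALSE)
  if ((cfg$species_per_genus - 1L) * cfg$within_genus_div > cfg$region_length)
    stop("within-genus divergence exceeds region length", call. = FALSE)
  if ((cfg$genera_per_family - 1L) * cfg$within_family_div > cfg$region_length)
    stop("within-family divergence exceeds region length", call. = FALSE)
  if (!is.null(cfg$season_assignment)) {
    if (length(cfg$season_assignment) != cfg$n_samples ||
        !all(cfg$season_assignment %in% SEASONS))
      stop("season_assignment must name one of the four seasons per sample",
           call. = FALSE)
  }
  if (!is.null(cfg$diet_profile)) {
    for (s in names(cfg$diet_profile)) {
      p <- cfg$diet_profile[[s]]
      if (length(p) == 0L) stop("empty diet profile for season ", s,
                                call. = FALSE)
      if (abs(sum(p) - 1) > 1e-9)
        stop("diet profile for season ", s, " must sum to 1", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Generate a toy flora and its reference sequence pool
#'
#' Builds a species -> genus -> family hierarchy with one barcode-region
#' sequence per species. Each family gets an independent random reference
#' sequence; each non-reference genus diverges from it by exactly
#' `within_family_div` substitutions, and each non-reference species diverges
#' from its genus reference by exactly `within_genus_div` substitutions, on
#' position blocks disjoint within the parent, so the configured divergences
#' are exact Hamming distances. Two bait species and two out-of-area
#' contaminant species (with unrelated random sequences) are appended.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_flora`: a list with `flora` (data.frame
#'   with columns species, genus, family, growth_form, in_area, is_bait),
#'   `pool` (data.frame with accession, species, tier, sequence), and the
#'   configuration used.
#' @export
generate_flora <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed %% .Machine$integer.max, {
    L <- cfg$region_length
    species <- genus <- family <- growth <- character(0)
    seqs <- character(0)
    for (f in seq_len(cfg$n_families)) {
      fam <- sprintf("Familia%02daceae", f)
      fam_root <- strsplit(random_sequence(L), "", fixed = TRUE)[[1]]
      # positions reserved for genus-level divergence, disjoint within family
      gpos <- if (cfg$genera_per_family > 1L && cfg$within_family_div > 0L)
        sample(L, (cfg$genera_per_family - 1L) * cfg$within_family_div)
      else integer(0)
      for (g in seq_len(cfg$genera_per_family)) {
        gen <- sprintf("Genus%02d%s", f, letters[g])
        groot <- fam_root
        if (g > 1L && cfg$within_family_div > 0L) {
          idx <- gpos[((g - 2L) * cfg$within_family_div + 1L):
                        ((g - 1L) * cfg$within_family_div)]
          groot <- mutate_positions(groot, idx)
        }
        spos <- if (cfg$species_per_genus > 1L && cfg$within_genus_div > 0L)
          sample(L, (cfg$species_per_genus - 1L) * cfg$within_genus_div)
        else integer(0)
        for (s in seq_len(cfg$species_per_genus)) {
          sp <- sprintf("%s species%02d", gen, s)
          sq <- groot
          if (s > 1L && cfg$within_genus_div > 0L) {
            idx <- spos[((s - 2L) * cfg$within_genus_div + 1L):
                          ((s - 1L) * cfg$within_genus_div)]
            sq <- mutate_positions(sq, idx)
          }
          species <- c(species, sp); genus <- c(genus, gen)
          family <- c(family, fam)
          growth <- c(growth, if (g %% 2L == 1L) "woody" else "herbaceous")
          seqs <- c(seqs, paste(sq, collapse = ""))
        }
      }
    }
    flora <- data.frame(
      species = species, genus = genus, family = family,
      growth_form = growth, in_area = TRUE, is_bait = FALSE,
      stringsAsFactors = FALSE
    )
    # bait species (trap bait; not part of the study-area diet)
    bait <- data.frame(
      species = c("Baitus cerealis", "Baitus nucifer"),
      genus = "Baitus", family = "Baitaceae",
      growth_form = c("herbaceous", "woody"),
      in_area = FALSE, is_bait = TRUE, stringsAsFactors = FALSE
    )
    # out-of-area contaminants (alpine taxa that cannot occur on site)
    contam <- data.frame(
      species = c("Alpinus nivalis", "Alpinus glacialis"),
      genus = "Alpinus", family = "Alpinaceae",
      growth_form = "herbaceous",
      in_area = FALSE, is_bait = FALSE, stringsAsFactors = FALSE
    )
    extra_seqs <- vapply(seq_len(4L), function(i) random_sequence(L), "")
    flora <- rbind(flora, bait, contam)
    seqs <- c(seqs, extra_seqs)
    pool <- data.frame(
      accession = sprintf("SYN%04d", seq_len(nrow(flora))),
      species = flora$species,
      tier = ifelse(flora$in_area, "local_survey", "external_pool"),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
    structure(list(flora = flora, pool = pool, cfg = cfg),
              class = "sim_flora")
  })
}

# Default seasonal diet profiles over the generated flora: five core species
# shared across seasons (summed weight 0.90) plus one season-specific species
# at weight 0.10.
default_diet_profile <- function(sim_flora) {
  fl <- sim_flora$flora
  candidates <- fl$species[fl$in_area]
  if (length(candidates) < 9L)
    stop("default diet profile needs at least 9 in-area species", call. = FALSE)
  core <- candidates[1:5]
  seasonal <- candidates[6:9]
  w_core <- c(0.30, 0.22, 0.18, 0.12, 0.08)
  out <- lapply(seq_along(SEASONS), function(i) {
    p <- c(w_core, 0.10)
    names(p) <- c(core, seasonal[i])
    p
  })
  names(out) <- SEASONS
  out
}

#' Simulate per-sample fecal amplicon reads with known ground truth
#'
#' Draws each sample's reads from its season's diet profile (multinomial),
#' then replaces a configured fraction with two-parent chimeras (prefix of one
#' diet read joined to the suffix of another at a uniform breakpoint),
#' bait-species copies and out-of-area contaminant copies, and finally applies
#' i.i.d. per-base substitution errors to every read. Every read carries
#' exactly one origin label in the ground truth.
#'
#' @param sim_flora output of [generate_flora()].
#' @param cfg a [sim_config()]; defaults to the configuration stored in
#'   `sim_flora`.
#' @return object of class `diet_sim`: list with `reads` (named list of
#'   character vectors, one per sample), `metadata` (data.frame sample_id,
#'   season, collection_month), `truth` (per-sample true taxon sets, per-read
#'   origin labels, per-taxon true frequency of occurrence) and `profile`.
#' @export
generate_samples <- function(sim_flora, cfg = sim_flora$cfg) {
  stopifnot(inherits(sim_flora, "sim_flora"), inherits(cfg, "sim_config"))
  fl <- sim_flora$flora
  seq_of <- stats::setNames(sim_flora$pool$sequence, sim_flora$pool$species)
  profile <- cfg$diet_profile %||% default_diet_profile(sim_flora)
  for (s in names(profile)) {
    if (length(profile[[s]]) == 0L)
      stop("empty diet profile for season ", s, call. = FALSE)
    missing <- setdiff(names(profile[[s]]), fl$species)
    if (length(missing))
      stop("diet profile references unknown taxa: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  seasons <- cfg$season_assignment %||%
    SEASONS[((seq_len(cfg$n_samples) - 1L) %% 4L) + 1L]
  bait_sp <- fl$species[fl$is_bait]
  contam_sp <- fl$species[!fl$in_area & !fl$is_bait]
  with_seed((cfg$seed + 1L) %% .Machine$integer.max, {
    L <- cfg$region_length
    months <- vapply(seq_len(cfg$n_samples), function(i) {
      m <- SEASON_MONTHS[[seasons[i]]]
      m[((i - 1L) %% length(m)) + 1L]
    }, integer(1))
    sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
    reads <- vector("list", cfg$n_samples)
    origins <- vector("list", cfg$n_samples)
    true_sets <- vector("list", cfg$n_samples)
    for (i in seq_len(cfg$n_samples)) {
      p <- profile[[seasons[i]]]
      n <- cfg$read_depth
      origin <- sample(c("diet", "chimera", "bait", "contaminant"), n,
                       replace = TRUE,
                       prob = c(1 - cfg$chimera_rate - cfg$bait_fraction -
                                  cfg$contaminant_fraction,
                                cfg$chimera_rate, cfg$bait_fraction,
                                cfg$contaminant_fraction))
      if (length(bait_sp) == 0L) origin[origin == "bait"] <- "diet"
      if (length(contam_sp) == 0L) origin[origin == "contaminant"] <- "diet"
      rd <- character(n)
      n_diet <- sum(origin == "diet")
      diet_taxa <- sample(names(p), n_diet, replace = TRUE, prob = p)
      rd[origin == "diet"] <- seq_of[diet_taxa]
      idx_ch <- which(origin == "chimera")
      if (length(idx_ch)) {
        donor <- rd[origin == "diet"]
        if (length(donor) < 2L)
          donor <- seq_of[sample(names(p), 2L, replace = TRUE, prob = p)]
        for (j in idx_ch) {
          pq <- sample(donor, 2L, replace = length(donor) < 2L)
          k <- sample.int(L - 1L, 1L)
          rd[j] <- paste0(substr(pq[1], 1L, k), substr(pq[2], k + 1L, L))
        }
      }
      idx_b <- which(origin == "bait")
      if (length(idx_b))
        rd[idx_b] <- seq_of[sample(bait_sp, length(idx_b), replace = TRUE)]
      idx_c <- which(origin == "contaminant")
      if (length(idx_c))
        rd[idx_c] <- seq_of[sample(contam_sp, length(idx_c), replace = TRUE)]
      # i.i.d. substitution errors over every emitted read
      if (cfg$error_rate > 0) {
        nerr <- stats::rbinom(n, L, cfg$error_rate)
        for (j in which(nerr > 0L)) {
          ch <- strsplit(rd[j], "", fixed = TRUE)[[1]]
          ch <- mutate_positions(ch, sample.int(L, nerr[j]))
          rd[j] <- paste(ch, collapse = "")
        }
      }
      reads[[i]] <- rd
      origins[[i]] <- origin
      true_sets[[i]] <- sort(unique(diet_taxa))
    }
    names(reads) <- names(origins) <- names(true_sets) <- sample_ids
    all_taxa <- sort(unique(unlist(true_sets)))
    true_fo <- vapply(all_taxa, function(t)
      sum(vapply(true_sets, function(s) t %in% s, logical(1))), numeric(1))
    truth <- list(
      taxa_per_sample = true_sets,
      origin = origins,
      fo_count = true_fo,
      fo_percent = pct1(100 * true_fo / cfg$n_samples)
    )
    metadata <- data.frame(sample_id = sample_ids, season = seasons,
                           collection_month = months,
                           stringsAsFactors = FALSE)
    structure(list(reads = reads, metadata = metadata, truth = truth,
                   profile = profile, cfg = cfg),
              class = "diet_sim")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTQ per sample (constant Q37 placeholder qualities), the
#' reference pool FASTA (`pool.fasta`, headers `accession|species|tier`), the
#' flora table (`flora.tsv`), sample metadata (`metadata.tsv`) and the ground
#' truth (`truth.json`).
#'
#' @param sim a `diet_sim` object.
#' @param sim_flora the matching `sim_flora` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, sim_flora, dir) {
  stopifnot(inherits(sim, "diet_sim"), inherits(sim_flora, "sim_flora"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$reads)) {
    rd <- sim$reads[[sid]]
    x <- Biostrings::DNAStringSet(rd)
    names(x) <- sprintf("%s_read%05d", sid, seq_along(rd))
    qual <- Biostrings::BStringSet(
      vapply(nchar(rd), function(n) strrep("F", n), ""))
    Biostrings::writeXStringSet(x, filepath = file.path(dir, paste0(sid, ".fastq")),
                                format = "fastq", qualities = qual)
  }
  pool <- Biostrings::DNAStringSet(sim_flora$pool$sequence)
  names(pool) <- with(sim_flora$pool, paste(accession, species, tier, sep = "|"))
  Biostrings::writeXStringSet(pool, file.path(dir, "pool.fasta"))
  utils::write.table(sim_flora$flora, file.path(dir, "flora.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read per-sample FASTQ files back into a read list
#'
#' @param dir directory holding `<sample_id>.fastq` files.
#' @param sample_ids sample ids to read; default: every `*.fastq` in `dir`.
#' @return named list of character vectors of reads.
#' @export
read_sample_fastq <- function(dir, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    files <- sort(list.files(dir, pattern = "\\.fastq$"))
    sample_ids <- sub("\\.fastq$", "", files)
  }
  out <- lapply(sample_ids, function(sid) {
    as.character(Biostrings::readDNAStringSet(
      file.path(dir, paste0(sid, ".fastq")), format = "fastq"))
  })
  names(out) <- sample_ids
  out
}
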