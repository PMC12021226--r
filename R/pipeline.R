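#' Run the full diet-metabarcoding pipeline on per-sample reads
#'
#' Convenience wrapper over the order-fixed stages: exact dereplication ->
#' two-parent chimera removal -> per-sample low-frequency filtering ->
#' rarefaction -> tiered taxonomic assignment -> diet table.
#'
#' @param reads named list sample id -> character vector of merged reads.
#' @param metadata data.frame with sample_id and season (or collection_month).
#' @param local_db curated local `ref_db` (bait-confound flags applied).
#' @param fallback_db external-pool `ref_db` or `NULL`.
#' @param flora flora data.frame.
#' @param cfg a [pipeline_config()]; its `depth`, `lowfreq`, `identity_gate`
#'   and `seed` drive the stages.
#' @param allow_list planted-ornamental allow-list for the fallback tier.
#' @return list with every intermediate: `raw`, `nochim`, `filtered`,
#'   `rarefied` (ASV tables), `assignments` (`asv_assignments`) and `diet`
#'   (`diet_table`).
#' @export
run_pipeline <- function(reads, metadata, local_db, fallback_db = NULL,
                         flora = local_db$flora, cfg = pipeline_config(),
                         allow_list = character(0)) {
  raw <- dereplicate(reads)
  nochim <- remove_chimeras(raw)
  filtered <- filter_low_frequency(nochim, threshold = cfg$lowfreq)
  rarefied <- rarefy_table(filtered, depth = cfg$depth, seed = cfg$seed)
  assignments <- assign_table(rarefied, local_db, fallback_db, flora, cfg,
                              allow_list)
  diet <- build_diet_table(assignments, rarefied, metadata, flora)
  list(raw = raw, nochim = nochim, filtered = filtered, rarefied = rarefied,
       assignments = assignments, diet = diet)
}

#' Build the local and fallback reference databases from a simulated flora
#'
#' The local database holds study-area species plus the bait species (as the
#' field database did); the fallback database stands in for the public
#' repository and holds every species in the pool.
#'
#' @param sim_flora a `sim_flora` object.
#' @return list with `local` and `fallback` `ref_db` objects, bait-confound
#'   flags applied to the local database.
#' @export
sim_databases <- function(sim_flora) {
  stopifnot(inherits(sim_flora, "sim_flora"))
  fl <- sim_flora$flora
  pool <- sim_flora$pool
  local_pool <- pool[pool$species %in% fl$species[fl$in_area | fl$is_bait], ,
                     drop = FALSE]
  local <- flag_bait_confounded(build_database(fl, local_pool))
  fallback <- build_database(fl, pool)
  list(local = local, fallback = fallback)
}
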