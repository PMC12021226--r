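# Shared fixtures: a 20-species toy flora, crafted sequence pools, and
# independent oracles used across the suite.

toy_flora <- function() {
  data.frame(
    species = c("Quercus acuta", "Quercus glauca", "Quercus myrsinifolia",
                "Quercus serrata", "Lithocarpus edulis", "Lithocarpus glaber",
                "Cinnamomum camphora", "Cinnamomum insularimontanum",
                "Machilus thunbergii", "Rubus hirsutus", "Rubus parvifolius",
                "Prunus serrulata", "Hordeum vulgare", "Bromus japonicus",
                "Ligustrum lucidum", "Ligustrum japonicum",
                "Fraxinus sieboldiana", "Taraxacum officinale",
                "Artemisia indica", "Farfugium japonicum"),
    genus = c(rep("Quercus", 4), rep("Lithocarpus", 2), rep("Cinnamomum", 2),
              "Machilus", rep("Rubus", 2), "Prunus", "Hordeum", "Bromus",
              rep("Ligustrum", 2), "Fraxinus", "Taraxacum", "Artemisia",
              "Farfugium"),
    family = c(rep("Fagaceae", 6), rep("Lauraceae", 3), rep("Rosaceae", 3),
               rep("Poaceae", 2), rep("Oleaceae", 3), rep("Asteraceae", 3)),
    growth_form = c(rep("woody", 12), rep("herbaceous", 2), rep("woody", 3),
                    rep("herbaceous", 3)),
    in_area = TRUE,
    is_bait = FALSE,
    stringsAsFactors = FALSE)
}

# Deterministic pseudo-random sequence of length L from a small seed.
fixed_seq <- function(L, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "rbcldiet")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                        collapse = ""))
}

# Substitute the bases at `pos` deterministically (A<->C, G<->T).
sub_at <- function(s, pos) {
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[pos] <- swap[ch[pos]]
  paste(ch, collapse = "")
}

make_pool <- function(species, sequences, tier = "local_survey") {
  data.frame(accession = sprintf("T%04d", seq_along(species)),
             species = species, tier = tier, sequence = sequences,
             stringsAsFactors = FALSE)
}

# Independent LCA oracle: intersect root-to-species taxonomy paths.
lca_oracle <- function(species_set, flora) {
  i <- match(unique(species_set), flora$species)
  paths <- lapply(i, function(j)
    c(flora$family[j], flora$genus[j], flora$species[j]))
  common <- Reduce(function(a, b) {
    k <- 0L
    while (k < min(length(a), length(b)) && a[k + 1L] == b[k + 1L])
      k <- k + 1L
    a[seq_len(k)]
  }, paths)
  if (!length(common)) return(list(rank = "none", name = NA_character_))
  rank <- c("family", "genus", "species")[length(common)]
  list(rank = rank, name = common[length(common)])
}

# Brute-force resolution-class oracle for a database entry.
resolution_oracle <- function(species_set, flora) {
  if (length(species_set) == 1L) return("species_specific")
  i <- match(species_set, flora$species)
  pairs <- utils::combn(seq_along(i), 2L)
  same_genus <- all(apply(pairs, 2, function(p)
    flora$genus[i[p[1]]] == flora$genus[i[p[2]]]))
  if (same_genus) return("genus_shared")
  same_family <- all(apply(pairs, 2, function(p)
    flora$family[i[p[1]]] == flora$family[i[p[2]]]))
  if (same_family) return("family_shared")
  "unassignable"
}
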