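test_that("percent identity follows the fixed alignment scoring", {
  s <- fixed_seq(262, 31)
  expect_equal(percent_identity(s, s), 100)
  expect_equal(percent_identity(s, sub_at(s, c(10, 50, 90, 130, 170))),
               100 * 257 / 262)
  expect_equal(percent_identity(s, sub_at(s, c(10, 50, 90, 130, 170, 210))),
               100 * 256 / 262)
  # gate arithmetic: 5 substitutions pass at 98, 6 fail
  expect_gte(100 * 257 / 262, 98)
  expect_lt(100 * 256 / 262, 98)
  # a single deletion costs one alignment column
  expect_equal(percent_identity(s, paste0(substr(s, 1, 99),
                                          substr(s, 101, 262))),
               100 * 261 / 262)
})

test_that("lowest common rank resolves sets as the taxonomy dictates", {
  fl <- toy_flora()
  expect_equal(lowest_common_rank("Cinnamomum camphora", fl),
               list(rank = "species", name = "Cinnamomum camphora"))
  expect_equal(lowest_common_rank(c("Quercus acuta", "Quercus glauca",
                                    "Quercus myrsinifolia",
                                    "Quercus serrata"), fl),
               list(rank = "genus", name = "Quercus"))
  expect_equal(lowest_common_rank(c("Lithocarpus edulis", "Quercus serrata"),
                                  fl),
               list(rank = "family", name = "Fagaceae"))
  expect_equal(lowest_common_rank(c("Quercus acuta", "Prunus serrulata"),
                                  fl)$rank, "none")
  expect_error(lowest_common_rank("Ficus imaginaria", fl), "not in taxonomy")
})

test_that("lowest common rank agrees with the path-intersection oracle", {
  fl <- toy_flora()
  for (size in 1:3) {
    sets <- utils::combn(fl$species, size, simplify = FALSE)
    for (s in sets) {
      expect_identical(lowest_common_rank(s, fl), lca_oracle(s, fl))
    }
  }
})

# A crafted reference world: local database over the toy flora with exact
# region-length sequences, 100 bp for easy identity arithmetic.
crafted_world <- function() {
  fl <- toy_flora()
  fl$is_bait[fl$species == "Hordeum vulgare"] <- TRUE
  fl$in_area[fl$species %in% c("Taraxacum officinale",
                               "Artemisia indica")] <- FALSE
  base <- fixed_seq(100, 41)
  seqs <- c(
    "Quercus acuta" = sub_at(base, 1:10),
    "Quercus glauca" = sub_at(base, 1:10),          # tied with Q. acuta
    "Prunus serrulata" = sub_at(base, 21:30),
    "Hordeum vulgare" = sub_at(base, 41:50),
    "Taraxacum officinale" = sub_at(base, 61:70),   # out of area
    "Artemisia indica" = sub_at(base, 76:85)        # out of area, planted
  )
  pool <- make_pool(names(seqs), unname(seqs))
  local <- flag_bait_confounded(
    build_database(fl, pool[pool$species %in%
                              c("Quercus acuta", "Quercus glauca",
                                "Prunus serrulata", "Hordeum vulgare"), ]))
  fallback <- build_database(fl, pool)
  list(fl = fl, seqs = seqs, local = local, fallback = fallback,
       cfg = pipeline_config(seed = 1))
}

test_that("tiered assignment implements the identification decision flow", {
  w <- crafted_world()
  # exact tie between two congeners resolves at genus on the local tier
  a <- assign_asv(unname(w$seqs["Quercus acuta"]), w$local, w$fallback,
                  w$fl, w$cfg)
  expect_equal(a$status, "assigned")
  expect_equal(a$tier, "local")
  expect_equal(a$rank, "genus")
  expect_equal(a$name, "Quercus")
  # bait match -> excluded_bait
  b <- assign_asv(unname(w$seqs["Hordeum vulgare"]), w$local, w$fallback,
                  w$fl, w$cfg)
  expect_equal(b$status, "excluded_bait")
  # out-of-area fallback match -> excluded_implausible
  c1 <- assign_asv(unname(w$seqs["Taraxacum officinale"]), w$local,
                   w$fallback, w$fl, w$cfg)
  expect_equal(c1$status, "excluded_implausible")
  expect_equal(c1$tier, "fallback")
  # the planted allow-list rescues an out-of-area taxon
  c2 <- assign_asv(unname(w$seqs["Artemisia indica"]), w$local, w$fallback,
                   w$fl, w$cfg, allow_list = "Artemisia indica")
  expect_equal(c2$status, "assigned")
  expect_equal(c2$name, "Artemisia indica")
  # below the gate everywhere -> unassigned
  far <- sub_at(fixed_seq(100, 41), 1:40)
  u <- assign_asv(far, w$local, w$fallback, w$fl, w$cfg)
  expect_equal(u$status, "unassigned")
})

test_that("a hit at exactly the gate passes", {
  w <- crafted_world()
  # 2 substitutions over 100 bp = exactly 98.0% identity
  query <- sub_at(unname(w$seqs["Prunus serrulata"]), c(55, 56))
  a <- assign_asv(query, w$local, w$fallback, w$fl, w$cfg)
  expect_equal(a$best_identity, 98)
  expect_equal(a$status, "assigned")
  # one more substitution drops below the gate on the local tier
  a2 <- assign_asv(sub_at(query, 57), w$local, NULL, w$fl, w$cfg)
  expect_equal(a2$status, "unassigned")
})

test_that("assignment is invariant to database entry order", {
  w <- crafted_world()
  shuffled <- w$local
  set.seed(5)
  shuffled$entries <- shuffled$entries[sample(nrow(shuffled$entries)), ]
  for (q in unname(w$seqs[c("Quercus acuta", "Prunus serrulata",
                            "Hordeum vulgare")])) {
    expect_equal(assign_asv(q, w$local, w$fallback, w$fl, w$cfg),
                 assign_asv(q, shuffled, w$fallback, w$fl, w$cfg))
  }
})

test_that("raising the gate never converts unassigned to assigned", {
  w <- crafted_world()
  queries <- c(unname(w$seqs), sub_at(unname(w$seqs["Prunus serrulata"]),
                                      1:5))
  gates <- c(90, 95, 98, 99, 100)
  status <- sapply(gates, function(g) {
    cfg <- pipeline_config(identity_gate = g, seed = 1)
    vapply(queries, function(q)
      assign_asv(q, w$local, w$fallback, w$fl, cfg)$status, "")
  })
  for (i in seq_along(queries)) {
    assigned <- status[i, ] != "unassigned"
    # once unassigned at some gate, higher gates stay unassigned
    expect_true(all(diff(as.integer(assigned)) <= 0))
  }
})

test_that("table-level assignment summarizes tiers and statuses", {
  w <- crafted_world()
  reads <- list(
    A = c(rep(unname(w$seqs["Quercus acuta"]), 60),
          rep(unname(w$seqs["Prunus serrulata"]), 30),
          rep(unname(w$seqs["Hordeum vulgare"]), 10)))
  tab <- dereplicate(reads)
  res <- assign_table(tab, w$local, w$fallback, w$fl, w$cfg)
  expect_equal(res$summary$n_asvs, 3L)
  expect_equal(res$summary$local_tier_count, 3L)
  expect_equal(res$summary$local_tier_percent, 100)
  st <- res$summary$by_status
  expect_equal(st$count[st$status == "assigned"], 2L)
  expect_equal(st$count[st$status == "excluded_bait"], 1L)
})
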