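# Shared fixture-derived objects: the published conserved/star tables as
# annotation hits, and the isomiR table driven through the variant chain
# (reference set = the reference entries printed alongside the variants).

fixture_hits_all <- function() {
  rbind(fixtureHits(mirbeanFixture("mature"), is_star = FALSE),
        fixtureHits(mirbeanFixture("star"), is_star = TRUE))
}

fixture_conserved_families <- function()
  unique(as.character(mirbeanFixture("mature")$family))

fixture_isomir_chain <- function() {
  t5 <- mirbeanFixture("isomir")
  libs <- c("LL", "FL", "RL", "SL")
  refs <- t5[t5$role == "reference", ]
  refdf <- data.frame(name = refs$name, family = mirFamily(refs$name),
                      sequence = refs$sequence,
                      is_star = grepl("[*]$", refs$name),
                      stringsAsFactors = FALSE)
  ref_totals <- setNames(rowSums(refs[, libs]), refs$name)
  vars <- t5[t5$role == "variant", ]
  tags <- TagSet(vars$sequence, as.matrix(vars[, libs]), libs)
  out <- isomirChain(tags, refdf, ref_totals, fixture_conserved_families())
  out$variant_names <- vars$name[match(out$calls$variant,
                                       normalizeRNA(vars$sequence))]
  out$printed_group <- vars$group[match(out$calls$variant,
                                        normalizeRNA(vars$sequence))]
  out
}

# 33-family count matrix mirroring the published expression input:
# conserved mature families plus the four promoted isomiR families
fixture_family_counts <- function() {
  chain <- fixture_isomir_chain()
  kept <- conservationFilter(fixture_hits_all())$kept
  poolFamilies(kept, promoted_calls = chain$calls[chain$calls$retained, ],
               promoted_families = chain$promoted,
               libraries = c("LL", "FL", "RL", "SL"))
}
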