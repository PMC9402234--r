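# Independent brute-force oracles, written against the data model only
# (plain loops, no cascade internals), used to cross-check the cascade and
# the exact test.

# First failing predicate in canonical stage order, or "survives_all".
# `panel_bed`/`panel_genes` are the raw interval/gene tables; `edges` the raw
# kinship edge data frame.
oracle_fate_one <- function(v, dosages, edges, panel_bed, panel_genes,
                            maf_threshold, phi_threshold,
                            cadd_min = 20, gerp_min = 3) {
  in_region <- FALSE
  for (r in seq_len(nrow(panel_bed))) {
    if (panel_bed$chrom[r] == v$chrom && panel_bed$start[r] <= v$pos &&
        v$pos < panel_bed$end[r]) {
      in_region <- TRUE
      break
    }
  }
  if (!(in_region && v$gene %in% panel_genes)) return("fails_panel")
  flags <- c(v$dbsnp, v$gnomad, v$topmed, v$kg1000, v$exac, v$gme, v$hgmd,
             v$clinvar)
  if (any(flags)) return("fails_novelty")
  if (v$cadd < cadd_min) return("fails_cadd")
  if (v$gerp < gerp_min) return("fails_gerp")
  ac <- sum(dosages, na.rm = TRUE)
  an <- 2 * sum(!is.na(dosages))
  maf <- if (an == 0) Inf else min(ac, an - ac) / an
  if (!(maf < maf_threshold)) return("fails_maf")
  if (ac < 2) return("fails_singleton")
  carriers <- names(dosages)[!is.na(dosages) & dosages >= 1]
  phi_pair <- function(x, y) {
    for (r in seq_len(nrow(edges))) {
      if ((edges$id1[r] == x && edges$id2[r] == y) ||
          (edges$id1[r] == y && edges$id2[r] == x)) return(edges$phi[r])
    }
    0
  }
  ok <- FALSE
  if (length(carriers) >= 2) {
    for (i in seq_len(length(carriers) - 1)) {
      for (j in (i + 1):length(carriers)) {
        if (phi_pair(carriers[i], carriers[j]) <= phi_threshold) ok <- TRUE
      }
    }
  }
  if (!ok) return("fails_unrelated")
  lof <- c("stop_gained", "stop_lost", "start_lost", "frameshift_variant",
           "splice_acceptor_variant", "splice_donor_variant")
  if (v$impact != "MODERATE" || v$effect %in% c("intron_variant", lof)) {
    return("fails_impact_effect")
  }
  "survives_all"
}

oracle_fates <- function(sim, panel, maf_threshold, phi_threshold = 0.0884) {
  vapply(seq_len(nrow(sim$variants)), function(i) {
    oracle_fate_one(as.list(sim$variants[i, ]),
                    sim$genotypes[, sim$variants$key[i]],
                    sim$kinship$edges, panel$intervals, panel$genes$gene,
                    maf_threshold, phi_threshold)
  }, character(1))
}

# Two-sided Fisher p by explicit enumeration with choose() arithmetic
# (distinct from the dhyper route used by the implementation).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, support) * choose(n - c1, r1 - support) / choose(n, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
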