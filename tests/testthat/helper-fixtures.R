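# small in-code fixtures shared across test files

make_gwas <- function(n = 3, trait_name = "trait", trait_type = "continuous",
                      snp_id = sprintf("rs%03d", seq_len(n)),
                      effect_allele = rep("A", n), other_allele = rep("G", n),
                      eaf = rep(0.3, n), beta = rep(0.1, n), se = rep(0.01, n),
                      pvalue = NULL, n_sample = rep(10000, n),
                      chrom = rep("1", n), pos = seq_len(n) * 1e6) {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  # fixtures often pair arbitrary p with arbitrary beta/se; silence the
  # consistency warning here (tested explicitly in the io tests)
  suppressWarnings(gwas_table(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                        effect_allele = effect_allele, other_allele = other_allele,
                        eaf = eaf, beta = beta, se = se, pvalue = pvalue,
                        n = n_sample, stringsAsFactors = FALSE),
             trait_name = trait_name, trait_type = trait_type))
}

make_iset <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                      se_Gamma = rep(0.1, length(gamma)),
                      snp_id = sprintf("rs%03d", seq_along(gamma))) {
  instrument_set(data.frame(snp_id = snp_id, gamma = gamma, se_gamma = se_gamma,
                            Gamma = Gamma, se_Gamma = se_Gamma,
                            stringsAsFactors = FALSE))
}

# selection cascade without the outcome-association exclusion, for
# experiments where pleiotropy must reach the estimators
prep_no_exclusion <- function(exp_tab, out_tab, ld, cfg = selection_config()) {
  sig <- suppressWarnings(filter_exposure_significant(exp_tab, cfg))
  cl <- suppressMessages(clump(sig, ld, cfg))
  filter_weak(harmonize(cl, out_tab, cfg), cfg)
}

quiet_select <- function(...) {
  suppressWarnings(suppressMessages(select_instruments(...)))
}
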