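# Small scenario builders shared across test files.

toy_strata <- function(freq = c(0.9, 0.1),
                       action = c("none", "dose_adjust"),
                       risk_untested = c(0.01, 0.05),
                       risk_tested = c(0.01, 0.02),
                       phenotype = paste0("P", seq_along(freq))) {
  phenotype_strata(phenotype = phenotype, frequency = freq, action = action,
                   risk_untested = risk_untested, risk_tested = risk_tested)
}

toy_scenario <- function(initiators = 1000, strata = toy_strata(),
                         test_cost = 50, drug_cost_soc = 100,
                         drug_cost_pgx = 100, certainty = 3,
                         drug = "toy-drug", gene = "TOYGENE") {
  dgi_scenario(drug = drug, gene = gene, initiators = initiators,
               strata = strata, test_cost = test_cost,
               drug_cost_soc = drug_cost_soc, drug_cost_pgx = drug_cost_pgx,
               certainty = certainty)
}

flat_schedule <- function(hcp = 16.39) {
  cost_schedule(hcp_cost_per_actionable = hcp)
}

dutch <- function() dutch_essential_portfolio()

dutch_scenario <- function(port, drug) {
  idx <- which(vapply(port$scenarios, function(s) s$drug, "") == drug)
  port$scenarios[[idx]]
}
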