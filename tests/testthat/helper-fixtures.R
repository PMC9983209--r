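# Shared fixture: a mid-sized panel with one strain pair, sized so that
# template-2 selection at the budgets used in tests is feasible.
fixture_panel <- function() {
  generate_panel(panel_config(
    n_organisms = 5, genes_per_organism = 400, gene_length = c(300, 600),
    fraction_shared_families = 0.3, within_family_sub_rate = 0.05,
    strain_pair_sub_rate = 0.02, fraction_single_copy = 0.1,
    n_strain_pairs = 1, seed = 11))
}

fixture_designer <- function(pan = fixture_panel(), budget = 450, seed = 3) {
  spec <- make_template(2, pan$organisms$org_id,
                        partner_pairs = pan$strain_pairs,
                        budget = budget, seed = seed)
  list(spec = spec, designer = select_contigs(spec, pan), panel = pan)
}
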