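# shared fixtures and small helpers

toyA <- function() toy_network("TOY-A")
toyB <- function(maintenance_lb = 0) toy_network("TOY-B", maintenance_lb)
toyC <- function() toy_network("TOY-C")

# weak-coupling style target on TOY-B: no product while growing
toyB_target <- function(model = toyB()) {
  linear_flux_space(rbind(-coupledesign:::.unit_row(model, "R_p"),
                          coupledesign:::.unit_row(model, "R_bio")),
                    c(0, 1), label = "toyB-test")
}

cutset_keys <- function(cutsets)
  sort(vapply(cutsets, function(x) paste(x$reactions, collapse = "+"), ""))

random_net_params <- function(form) {
  switch(form,
    MCSe = formulation_params("MCSe", product = "R_p", substrate = "R_s",
                              atpm = "R_m", s_max = 10, y_min = 0.3,
                              m_atp = 0.5),
    MCSf = formulation_params("MCSf", product = "R_p", substrate = "R_s",
                              s_max = 10, y_min = 0.3),
    MCSw = formulation_params("MCSw", product = "R_p", biomass = "R_bio",
                              eps = 1e-4, F = 0.1))
}
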