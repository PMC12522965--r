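# shared fixtures: all built in code, no stored data

default_params <- function(...) load_parameter_table(settings = list(...))

# independent oracle: discounted geometric series summed term by term
geom_sum <- function(p, r, n = 5000) sum((p / (1 + r))^(0:n))

table3 <- list(icd = c(cost = 41135, effect = 12.63),
               pharm = c(cost = 8592, effect = 11.29))
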