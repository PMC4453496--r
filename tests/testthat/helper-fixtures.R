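# Ten hand-built children covering every inclusion filter.
growth_fixture <- function() {
  lin <- function(ages, a, b) a + b * ages          # exact line, SE 0
  kids <- list(
    ok_linear   = list(age = c(0.1, 0.4, 0.8, 1.2, 1.6, 1.9),
                       z = lin(c(0.1, 0.4, 0.8, 1.2, 1.6, 1.9), -1, 0.5)),
    too_few     = list(age = c(0.2, 0.7, 1.3, 1.8), z = c(0, 0.1, 0.2, 0.3)),
    no_year2    = list(age = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.95),
                       z = c(0, 0.1, 0, 0.2, 0.1, 0.3)),
    no_year1    = list(age = c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0),
                       z = c(0, 0.1, 0, 0.2, 0.1, 0.3)),
    zero_var    = list(age = rep(1.0, 5), z = c(0, 0.1, 0.2, 0.3, 0.4)),
    noisy       = list(age = c(0.2, 0.6, 1.0, 1.4, 1.8),
                       z = c(0, 2, -2, 2, -2)),          # SE = sqrt(3) >= 0.4
    ok_noisy    = list(age = c(0.1, 0.5, 0.9, 1.1, 1.5, 1.9),
                       z = c(-0.5, -0.4, -0.45, -0.3, -0.25, -0.2)),
    ok_flat     = list(age = c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8),
                       z = rep(0.2, 6)),
    ok_negative = list(age = c(0.05, 0.45, 0.85, 1.25, 1.65),
                       z = lin(c(0.05, 0.45, 0.85, 1.25, 1.65), 1, -0.8)),
    ok_mixed    = list(age = c(0, 0.3, 0.7, 1.0, 1.4, 1.7, 2.0),
                       z = c(0.1, 0.2, 0.15, 0.3, 0.35, 0.3, 0.5))
  )
  kids
}
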