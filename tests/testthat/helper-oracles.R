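# Literal term-by-term transcription of the circuit equations, written
# independently of circuit_rhs() and kept deliberately naive: every current
# is spelled out against the published symbol set.
oracle_rhs <- function(s, V_ret, p) {
  sig <- function(V, tp) tp$T_max / (1 + exp(-(V - tp$theta_s) / tp$sigma_s))
  T_ret <- sig(V_ret, p$transmitter$ret)
  T_tcr <- sig(s[1], p$transmitter$tcr)
  T_trn <- sig(s[2], p$transmitter$trn)

  d3 <- p$ampa_ret$alpha * T_ret * (1 - s[3]) - p$ampa_ret$beta * s[3]
  d4 <- p$gabaa_n2t$alpha * T_trn * (1 - s[4]) - p$gabaa_n2t$beta * s[4]
  d5 <- p$gabab_n2t$alpha1 * T_trn * (1 - s[5]) - p$gabab_n2t$beta1 * s[5]
  d6 <- p$gabab_n2t$alpha2 * s[5] - p$gabab_n2t$beta2 * s[6]
  d7 <- p$ampa_t2n$alpha * T_tcr * (1 - s[7]) - p$ampa_t2n$beta * s[7]
  d8 <- p$gabaa_n2n$alpha * T_trn * (1 - s[8]) - p$gabaa_n2n$beta * s[8]

  rB <- s[6]^p$gabab_n2t$n / (s[6]^p$gabab_n2t$n + p$gabab_n2t$K_d)
  I1 <- p$ampa_ret$g_max * s[3] * (s[1] - p$ampa_ret$V_rev)
  I2 <- p$gabaa_n2t$g_max * s[4] * (s[1] - p$gabaa_n2t$V_rev)
  I3 <- p$gabab_n2t$g_max * rB * (s[1] - p$gabab_n2t$V_rev)
  d1 <- (-(p$conn$C_tre * I1 + p$conn$C_tni_a * I2 + p$conn$C_tni_b * I3) -
         p$tcr$g_leak * (s[1] - p$tcr$V_leak)) / p$tcr$kappa_m
  I4 <- p$ampa_t2n$g_max * s[7] * (s[2] - p$ampa_t2n$V_rev)
  I5 <- p$gabaa_n2n$g_max * s[8] * (s[2] - p$gabaa_n2n$V_rev)
  d6b <- (-(p$conn$C_nte * I4 + p$conn$C_nsi * I5) -
          p$trn$g_leak * (s[2] - p$trn$V_leak)) / p$trn$kappa_m
  c(d1, d6b, d3, d4, d5, d6, d7, d8)
}

rand_state <- function() {
  c(runif(2, -100, 0), runif(2), runif(1), runif(1, 0, 10), runif(2))
}
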