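# Independent brute-force oracle for the one-sided Fisher somatic p:
# explicit hypergeometric tail enumeration from binomial coefficients,
# sharing no code path with the implementation under test.
fisher_tail_oracle <- function(case_ref, case_alt, ctrl_ref, ctrl_alt) {
  N <- case_ref + case_alt + ctrl_ref + ctrl_alt
  if (N == 0) return(1)
  m <- case_alt + ctrl_alt   # total variant reads across both samples
  k <- case_ref + case_alt   # case row margin
  j <- case_alt:min(m, k)
  sum(exp(lchoose(m, j) + lchoose(N - m, k - j) - lchoose(N, k)))
}
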