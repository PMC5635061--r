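# Frozen reference values for the worked fixture (see worked_fixture()),
# computed once at package-build time from independent brute-force oracles:
# a double-loop pairwise CKA estimator, central finite differences (h = 1e-6)
# for the gradient at the initialization, and an elementwise
# mean-of-absolute-values for the relevance of the initial projection.
.fixture_reference <- list(
  cka_init = 0.748945529572602,
  grad_A_init = matrix(c(
     0.4056864212, -0.4765221696,  0.1995585668,  0.0621518836,
     0.1724497987,  0.2261981926, -0.1819953462, -0.4001341469,
    -0.0628991021, -0.4149763373), nrow = 5, ncol = 2),
  grad_log_sigma_init = -0.0451080384,
  relevance_init = c(0.46709547886813962, 0.50316771234746771,
                     0.47989958474793121, 0.06582583041481288,
                     0.48988835264054059))
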