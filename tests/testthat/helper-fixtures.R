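# Small parameter sets and regimens shared across tests.

test_params <- function(ka = 1.2, V1 = 30, k12 = 0.25, k21 = 0.12,
                        CLint_h = 400, CLr = 0.5, FaFg = 0.5,
                        fu_b = 0.05, MW = 500, ...) {
  compartmental_params(ka = ka, V1 = V1, k12 = k12, k21 = k21,
                       CLint_h = CLint_h, CLr = CLr, FaFg = FaFg,
                       fu_b = fu_b, MW = MW, ...)
}

single_oral <- function(amount = 100, time = 0)
  pk_regimen(dose_event(amount, time), cycle_length = 24)

# log-uniform random parameter draws within physiological-ish ranges
random_params <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  test_params(ka = lu(0.2, 4), V1 = lu(5, 200), k12 = lu(0.02, 1),
              k21 = lu(0.02, 1), CLint_h = lu(5, 2000),
              CLr = lu(0.001, 5), FaFg = stats::runif(1, 0.2, 1),
              fu_b = stats::runif(1, 0.01, 0.9))
}
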