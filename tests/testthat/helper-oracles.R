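# Longhand least-squares slope via the normal equations, independent of lm()
ols_slope_longhand <- function(x, y) {
  xbar <- sum(x) / length(x)
  ybar <- sum(y) / length(y)
  sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
}

# a plain ratio series for conversion tests: value = intercept + slope * t
ratio_series <- function(slope, times = c(0, 1, 2, 5, 8),
                         intercept = 0.011, ...) {
  incubation_series(times, intercept + slope * times,
                    observable = "co2_ratio", ...)
}
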