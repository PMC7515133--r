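#' @export
print.prd_point <- function(x, ...) {
  cat(sprintf("lambda=%.4g  rate=%.4f  loss=%.4f  predictiveness=%.4f  objective=%.4f nats\n",
              x$lambda, x$rate, x$loss, x$predictiveness, x$objective))
  if (!is.na(x$se_rate))
    cat(sprintf("  SE(rate)=%.4f  SE(loss)=%.4f  SE(pred)=%.4f\n",
                x$se_rate, x$se_loss, x$se_predictiveness))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
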