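pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

# Closure fitting an encoding model on one voxel and scoring on the test set;
# the shape permutation_test() expects.
encoding_scorer <- function(tr, te) {
  m <- fit_encoding(tr$x, tr$y)
  evaluate(m, te$y, te$x)$r
}
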