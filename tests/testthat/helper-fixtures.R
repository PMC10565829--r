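# Shared fixtures, built once per test run and cached (model training and
# scheme generation are the expensive pieces).

.fx <- new.env(parent = emptyenv())

fx_bank <- function() {
  if (is.null(.fx$bank)) .fx$bank <- build_element_bank(seed = 101)
  .fx$bank
}

fx_patch_data <- function() {
  if (is.null(.fx$patch_data)) {
    .fx$patch_data <- make_arrow_patch_dataset(n_arrow = 125, n_negative = 125,
                                               seed = 42)
  }
  .fx$patch_data
}

# fixed 200/50 split of the patch dataset
fx_patch_split <- function() {
  ds <- fx_patch_data()
  n <- length(ds$patches)
  idx <- rxnscheme:::with_seed(99, sample(n))
  list(train = idx[1:200], test = idx[201:n])
}

fx_arrow_model <- function() {
  if (is.null(.fx$arrow_model)) {
    sp <- fx_patch_split()
    ds <- fx_patch_data()
    .fx$arrow_model <- train_arrow_model(ds$patches[sp$train],
                                         ds$labels[sp$train],
                                         epochs = 20, lr = 0.001, seed = 7)
  }
  .fx$arrow_model
}

fx_scheme <- function(seed = 11, n_steps = 2, p_label = 1, p_conditions = 1,
                      layout = "linear", diagrams_per_step = c(1, 2), ...) {
  sch <- schema_spec(layout, n_steps = n_steps,
                     diagrams_per_step = diagrams_per_step,
                     p_label = p_label, p_conditions = p_conditions, ...)
  compose_scheme(sch, fx_bank(), seed = seed)
}
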