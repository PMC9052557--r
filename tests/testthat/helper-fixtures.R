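# shared fixtures: built in code, no files

# life table with constant annual death probability q at every age
flat_life_table <- function(q = 0.1, max_age = 120) {
  lt <- data.frame(age = 0:max_age, male = q, female = q)
  lt$male[nrow(lt)] <- 1
  lt$female[nrow(lt)] <- 1
  class(lt) <- c("namd_life_table", "data.frame")
  lt
}

# identity transition matrices (no VA movement)
identity_matrices <- function() {
  m <- build_transition_matrix(c(0, 0, 1, 0, 0))
  list(year1 = m, year2plus = m)
}

with_settings <- function(p, ...) {
  namdcea:::merge_params(p, list(settings = list(...)))
}

p_default <- default_parameter_set()
lt_synth <- generate_life_table()
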