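# shared fixture builders: everything is generated in code at test time

# single-subject dense profile from explicit (time, conc) values
profile_of <- function(time, conc, subject = "s1") {
  pool(concentration_records(rep(subject, length(time)), time, conc))
}

# noise-free one-compartment profile sampled at the given times
onecomp_profile <- function(params, times) {
  profile_of(times, predict_concentration(params, times))
}

# write a small long-format CSV and return its path
write_toy_long <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(c("subject,time_h,conc_ug_ml", lines), file)
  file
}

# per-time means of the packaged study table (computed by pool() elsewhere;
# used as raw input where a test needs the mean profile as plain numbers)
study_mean_profile <- function() {
  data.frame(time = c(0, 1, 2, 4, 8, 12, 24),
             conc = c(0, 1.9, 2.22, 1.88, 1.0, 0.4, 0.216))
}
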