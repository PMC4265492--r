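# shipped synthetic 10-segment lung (fixture F1)
f1Table <- function() {
  read.csv(system.file("extdata", "segments_f1.csv", package = "stepup"),
           stringsAsFactors = FALSE)
}

# uniform-HU phantom built directly, for exact-value densitometry checks
uniformPhantom <- function(hu_values, voxel_volume = 0.001,
                           segment_id = "RB1") {
  n <- length(hu_values)
  d <- ceiling(n^(1 / 3))
  hu <- array(-1000, dim = c(d, d, d))
  labels <- array(0L, dim = c(d, d, d))
  hu[seq_len(n)] <- hu_values
  labels[seq_len(n)] <- 1L
  new("VoxelPhantom", hu = hu, labels = labels,
      voxelVolume = voxel_volume,
      labelTable = data.frame(label = 1L, segment_id = segment_id))
}

# fully eligible reference patient for the screening tests
eligibleRecord <- function(...) {
  args <- list(age = 60, fev1_pct_pred = 35, tlc_pct_pred = 105,
               rv_pct_pred = 180, six_mwd = 250, mmrc = 3, paco2 = 45,
               pao2 = 60, bmi = 25, dlco_pct_pred = 35,
               lower_lobe_tar = 13)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(patientRecord, args)
}
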