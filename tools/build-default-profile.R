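# Regenerates inst/extdata/wd40_profile_default_synthetic.txt from the
# in-code specification. Run from the package root:
#   Rscript tools/build-default-profile.R
pkgload::load_all(".", quiet = TRUE)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeRepeatProfile(makeDefaultProfile(),
                   "inst/extdata/wd40_profile_default_synthetic.txt")
cat("wrote inst/extdata/wd40_profile_default_synthetic.txt\n")
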