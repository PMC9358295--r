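# Default intensities of the Na+/HCO3- cotransporters (mol/m^2/s).
# These two intensities are not available from direct measurement; they are
# calibrated once so that the baseline steady state reproduces the reference
# composition, potentials and fluxes (see the methods vignette for the
# procedure and the residual misfit).
.NBC_DEFAULTS <- c(P_nbcp = 1.423e-6, P_nbcs = 5.901e-7)
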