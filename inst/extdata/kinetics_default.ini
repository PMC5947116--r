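# Default channel kinetics for the stellate-cell model.
#
# RECONSTRUCTION NOTICE.  The published description of this model prints
# the membrane equation, the conductance/reversal table and the AHP
# kinetics, but delegates the voltage-dependent rate functions of the six
# standard channels (NaT, NaP, Kdr, Kaf, Kas, h) to an earlier stellate-cell
# model that is not distributed with this package.  The rates below are a
# documented reconstruction: Traub-Miles-type spike currents (NaT, Kdr),
# first-order sigmoid gates for the persistent sodium (NaP, slow
# activation), the A-type potassium currents (Kaf fast, Kas slow
# inactivation) and the hyperpolarisation-activated cation current (h,
# single component).  Constants were fixed once so that the model
# reproduces the qualitative regime structure reported for the original:
# a stable rest at low gh or low Iapp that is marginally lost at the
# standard operating point (Table values, gh = 2.8, gAHP = 0.425,
# Iapp = 0.3), tonic firing at low gAHP / high gh, periodic three-spike
# bursting at the operating point via a subcritical-Hopf/homoclinic
# fast-slow mechanism with mNaP and hKas slow, and a subthreshold
# theta-band focus below the Iapp fold.  Quantitative bifurcation
# landmarks are contingent on this file; see the package vignette.
#
# Open questions carried from the source description (flagged, not guessed
# silently): whether the h current has one or two (fast/slow) components --
# a single component is used here; whether the AHP open fraction enters the
# current with exponent 1 -- exponent 1 is used.
#
# Units: V in mV, rates in 1/ms, g in mS/cm^2, E in mV.  The AHP gate's
# opening rate is a function of t = time since the last spike (ms); its
# expressions are regenerated from the scalar AHP parameters at model
# construction.
version = 1

[NaT]
g = 24
E = 55
gate m 3
alpha_m = 0.32*(V+52)/(1-exp(-(V+52)/4))
beta_m = 0.28*(V+25)/(exp((V+25)/5)-1)
gate h 1
alpha_h = 0.128*exp(-(V+48)/18)
beta_h = 4/(1+exp(-(V+25)/5))

[NaP]
g = 0.075
E = 55
gate m 1
alpha_m = (1/(150+950/(1+exp((V+63)/2.5))))/(1+exp(-(V+54.8)/4))
beta_m = (1/(150+950/(1+exp((V+63)/2.5))))/(1+exp((V+54.8)/4))

[Kdr]
g = 11
E = -85
gate n 4
alpha_n = 0.032*(V+50)/(1-exp(-(V+50)/5))
beta_n = 0.5*exp(-(V+55)/40)

[Kaf]
g = 0.1
E = -85
gate m 1
alpha_m = (1/2)/(1+exp(-(V+35)/8))
beta_m = (1/2)/(1+exp((V+35)/8))
gate h 1
alpha_h = (1/30)/(1+exp((V+68)/6))
beta_h = (1/30)/(1+exp(-(V+68)/6))

[Kas]
g = 0.5
E = -85
gate m 1
alpha_m = (1/10)/(1+exp(-(V+52)/6))
beta_m = (1/10)/(1+exp((V+52)/6))
gate h 1
alpha_h = (1/600)/(1+exp((V+66)/5))
beta_h = (1/600)/(1+exp(-(V+66)/5))

[h]
g = 2.8
E = -30
gate n 1
alpha_n = (1/(1+exp((V+76.5)/5)))/(1+90/(exp((V+52)/9)+exp(-(V+95)/20)))
beta_n = (1-1/(1+exp((V+76.5)/5)))/(1+90/(exp((V+52)/9)+exp(-(V+95)/20)))

[AHP]
g = 0.425
E = -85
gate n 1
alpha_n = 1.5*exp(-t/60)
beta_n = 1.6

[L]
g = 0.15
E = -88.5
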