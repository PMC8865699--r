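#ifndef ENGRAMNET_SIEGERT_H
#define ENGRAMNET_SIEGERT_H

double en_erfcx(double x);
// stationary LIF rate (spikes/s); times in seconds, potentials in mV
double en_siegert(double mu, double sigma, double tau_m_s, double t_ref_s,
                  double v_th, double v_r);

#endif
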