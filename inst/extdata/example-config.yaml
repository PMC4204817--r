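# Default fully-defined signal mixture experiment.
# Units: kernels/windows in ms, spike times and durations in s,
# currents in pA, voltages in mV.
paradigm: mixture
seed: 1
population:
  n_total: 1024        # 512 excitatory + 512 inhibitory model inputs
  e_fraction: 0.5
renewal:
  shape: 2             # gamma shape k (ISI CV^2 = 1/k)
  rate: 5              # mean presynaptic rate, Hz
  min_isi: 10          # resampling floor, ms
amplitude:
  mu_log: 0.702        # log-normal PSC amplitude parameters (log-pA)
  sigma_log: 0.9355
  n_levels: 32         # discrete log-spaced amplitude classes
  span_sd: 3.5         # half-range of the discretization, in sigma_log
kernel:
  tau_rise: 0.5        # PSC rise time constant, ms
  tau_decay: 5         # PSC decay time constant, ms
  dt: 0.05             # 20 kHz sample grid
current:
  target_sd: 100       # SD of the scaled fluctuating current, pA
  dc: ~                # null = calibrate to neuron.target_rate
episodes:
  n: 31
  duration_s: 46
  discard_s: 2
neuron:
  tau_m: 20
  r_in: 140
  v_rest: -70
  v_thresh: -50
  v_reset: -60
  t_ref: 3
  target_rate: 5       # Hz, used to calibrate the DC offset
analysis:
  # T_grid defaults to 0.4 ms .. 15 ms in 0.4 ms steps when omitted
  N_list: [250, 500, 1000, 2000]
  method: parametric
  alpha: 0.05
  n_sets: 100
  n_reps: 100
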