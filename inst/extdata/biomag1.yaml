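# biomag1: reference configuration of the 3 L magnetic-retention bench
# bioreactor. Geometry in cm, currents in A, flux density in T; keys carry
# their units. load_config() normalizes everything to SI.

name: biomag1

array:
  n_coils: 3                # triangular arrangement under the vessel
  arrangement: triangular
  total_current_A: 10.0     # supply limit, split across the parallel coils
  coil:
    inner_radius_cm: 5.0    # selected radius: saturates the core yet holds
                            # field at 10 cm height
    height_cm: 4.0          # matches the stacked-disc core height
    turns: 300              # tripled turns at one-third current keeps N*I
                            # while cutting resistive heating
    wire_awg: 20            # thinnest gauge reaching 10 A under 15 V per coil
    wire_pitch_mm: 0.9      # 0.8128 mm bare diameter + enamel allowance
  core:
    radius_cm: 5.0
    height_cm: 4.0          # laser-cut 2 mm A36 discs stacked to 4 cm
    mu_r: 200.0             # assumed relative permeability of A36 low-carbon steel
    b_sat_T: 2.16           # A36 saturation flux density

container:
  volume_L: 3.0
  diameter_cm: 16.0
  height_cm: 20.0
  liquid_height_cm: 10.0    # design height at which 0.2 T must be available

sizing:
  heater:
    mass_g: 2500.0          # water mass for the heater sizing balance
    t_initial_C: 25.0
    t_final_C: 50.0
    heating_time_min: 5.0
    cp_J_per_gK: 4.1806     # specific heat of water
  mixing:
    fluid_density_kg_m3: 1000.0   # water as stand-in for the working substance
    dynamic_viscosity_Pa_s: 0.001
    impeller_diameter_cm: 10.0    # Rushton turbine
    speed_rpm: 100.0              # rated speed
    power_number: 5.0             # standard curve value for this stirrer
  wire:
    mass_lb: 0.33333333333333     # one third of a pound per coil at the
                                  # design stage
    current_A: 10.0
    v_max_V: 15.0                 # supply voltage ceiling
    candidates_awg: [16, 18, 20, 22]

control:
  temperature:
    gain_C_per_V: 1.475     # identified first-order-plus-dead-time plant
    time_constant_s: 990.0
    dead_time_s: 120.0
    ambient_C: 25.0
    pid: {kp: 3.3, ki: 0.0033, kd: 82.5}
    v_line_V: 120.0         # grid voltage chopped by the AC relay
    duty_period_s: 5.0
    setpoints_C: [35.0, 50.0]
  ph:
    volume_L: 3.0
    acid_M: 0.47            # HCl titrant
    base_M: 0.5             # NaOH titrant
    drop_uL: 50.0           # 20 drops per mL drip chamber
    pulse_s: 3.0            # valve-open time per correction
    drop_rate_per_s: 1.0    # flow in the open configuration
    settle_s: 5.0           # mixing wait before re-reading
    noise_sd: 0.05
    filter_window: 5
    scenarios:
      - {initial_ph: 7.0, band: [4.5, 5.5]}   # acid operating range
      - {initial_ph: 6.0, band: [7.0, 8.0]}   # alkaline operating range
  stirrer:
    gain_rpm: 130.0         # full-drive speed of the geared DC motor model
    time_constant_s: 0.3
    noise_sd_rpm: 2.0
    filter_window: 5
    pid: {kp: 0.18, ki: 0.8, kd: 0.0016}
    setpoints_rpm: [25.0, 50.0, 100.0]
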