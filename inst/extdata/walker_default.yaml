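schema: gaitenv-model-1
gravity: 9.80665
segments:
  pelvis:
    mass: 50.8
    inertia: 3.0
    com:
    - 0.0
    - 0.3
  thigh:
    mass: 7.5
    inertia: 0.135
    length: 0.44
    com:
    - 0.0
    - -0.19
  shank:
    mass: 3.5
    inertia: 0.058
    length: 0.43
    com:
    - 0.0
    - -0.19
  foot:
    mass: 1.2
    inertia: 0.007
    com:
    - 0.06
    - -0.04
joints:
  hip:
    limits:
    - -0.87
    - 2.09
    stiffness: 300.0
    damping: 30.0
  knee:
    limits:
    - -2.4
    - 0.02
    stiffness: 300.0
    damping: 30.0
  ankle:
    limits:
    - -0.9
    - 0.7
    stiffness: 300.0
    damping: 30.0
contact:
  stiffness: 1200000.0
  exponent: 1.5
  damping: 1.0
  friction_mu: 0.8
  friction_vsmooth: 0.05
  spheres:
    heel:
      pos:
      - -0.07
      - -0.05
      radius: 0.025
    mid:
      pos:
      - 0.055
      - -0.05
      radius: 0.025
    toe:
      pos:
      - 0.18
      - -0.05
      radius: 0.025
muscles:
  HAB_R:
    f_max: 3000.0
    l_opt: 0.09
    v_max: 12.0
    l_slack: 0.13
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.0
  HAD_R:
    f_max: 4500.0
    l_opt: 0.1
    v_max: 12.0
    l_slack: 0.17
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.0
  HFL_R:
    f_max: 2000.0
    l_opt: 0.11
    v_max: 12.0
    l_slack: 0.1
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.08
      knee: 0.0
      ankle: 0.0
  GLU_R:
    f_max: 1500.0
    l_opt: 0.11
    v_max: 12.0
    l_slack: 0.13
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: -0.08
      knee: 0.0
      ankle: 0.0
  HAM_R:
    f_max: 3000.0
    l_opt: 0.1
    v_max: 12.0
    l_slack: 0.31
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: -0.08
      knee: -0.05
      ankle: 0.0
  RF_R:
    f_max: 1200.0
    l_opt: 0.08
    v_max: 12.0
    l_slack: 0.35
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.08
      knee: 0.06
      ankle: 0.0
  VAS_R:
    f_max: 6000.0
    l_opt: 0.08
    v_max: 12.0
    l_slack: 0.23
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.06
      ankle: 0.0
  BFSH_R:
    f_max: 350.0
    l_opt: 0.12
    v_max: 12.0
    l_slack: 0.1
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: -0.04
      ankle: 0.0
  GAS_R:
    f_max: 1500.0
    l_opt: 0.05
    v_max: 12.0
    l_slack: 0.4
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: -0.05
      ankle: -0.05
  SOL_R:
    f_max: 4000.0
    l_opt: 0.04
    v_max: 6.0
    l_slack: 0.26
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: -0.05
  TA_R:
    f_max: 800.0
    l_opt: 0.06
    v_max: 12.0
    l_slack: 0.24
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.04
  HAB_L:
    f_max: 3000.0
    l_opt: 0.09
    v_max: 12.0
    l_slack: 0.13
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.0
  HAD_L:
    f_max: 4500.0
    l_opt: 0.1
    v_max: 12.0
    l_slack: 0.17
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.0
  HFL_L:
    f_max: 2000.0
    l_opt: 0.11
    v_max: 12.0
    l_slack: 0.1
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.08
      knee: 0.0
      ankle: 0.0
  GLU_L:
    f_max: 1500.0
    l_opt: 0.11
    v_max: 12.0
    l_slack: 0.13
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: -0.08
      knee: 0.0
      ankle: 0.0
  HAM_L:
    f_max: 3000.0
    l_opt: 0.1
    v_max: 12.0
    l_slack: 0.31
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: -0.08
      knee: -0.05
      ankle: 0.0
  RF_L:
    f_max: 1200.0
    l_opt: 0.08
    v_max: 12.0
    l_slack: 0.35
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.08
      knee: 0.06
      ankle: 0.0
  VAS_L:
    f_max: 6000.0
    l_opt: 0.08
    v_max: 12.0
    l_slack: 0.23
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.06
      ankle: 0.0
  BFSH_L:
    f_max: 350.0
    l_opt: 0.12
    v_max: 12.0
    l_slack: 0.1
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: -0.04
      ankle: 0.0
  GAS_L:
    f_max: 1500.0
    l_opt: 0.05
    v_max: 12.0
    l_slack: 0.4
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: -0.05
      ankle: -0.05
  SOL_L:
    f_max: 4000.0
    l_opt: 0.04
    v_max: 6.0
    l_slack: 0.26
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: -0.05
  TA_L:
    f_max: 800.0
    l_opt: 0.06
    v_max: 12.0
    l_slack: 0.24
    tau_act: 0.015
    tau_deact: 0.05
    fv_ecc_plateau: 1.5
    moment_arm:
      hip: 0.0
      knee: 0.0
      ankle: 0.04
simulation:
  dt: 0.01
  substeps: 10.0
  init_height: 0.9428
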