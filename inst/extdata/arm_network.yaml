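# Generic adult upper-body vascular network (reference subject: male, 50 y,
# 176 cm, 75 kg, BP 130/75 mmHg).
#
# The access-arm arterial and venous trees are fully resolved; the remainder
# of the systemic circulation is lumped into the systemic-bed terminal at the
# subclavian origin. All numeric entries are physiologic stand-ins assembled
# from standard anatomical/hemodynamic reference ranges (textbook adult
# values), documented inline; they are deliberately editable: the model reads
# whatever file it is given.
#
# Units: length_cm (cm), radius_mm (lumen radius, mm), wall_mm (wall
# thickness, mm), stiffness_MPa (effective elastic modulus, MPa),
# resistance_mmHg_min_ml (mmHg*min/mL). Terminals drain to the extravascular
# reference pressure, fixed at 0 mmHg.
#
# Terminal resistances are set so that at rest (CO ~5.7 L/min for the
# reference subject) the arm receives ~100 mL/min through the brachial artery
# (hand beds ~30 mL/min each, forearm beds ~25, upper arm ~20) at a mean
# arterial pressure of ~93 mmHg, with the rest of the cardiac output taken by
# the lumped systemic bed.

schema: avfsim-network/1
inlet_node: aortic-root

segments:
  # ---- arteries -----------------------------------------------------------
  - id: central-artery            # ascending aorta/arch to subclavian origin
    vessel_class: artery
    proximal_node: aortic-root
    distal_node: n-aorta
    length_cm: 20
    radius_mm: 10.0               # adult aortic arch lumen radius
    wall_mm: 1.5
    stiffness_MPa: 0.4
    adapting: false
  # lumped conduit + storage of the remaining systemic arterial tree
  # (descending aorta and branches); its compliance carries the windkessel
  # storage (~1e-8 m^3/Pa total arterial compliance) that sets the pulse
  # pressure, which a single straight aorta segment cannot represent
  - id: systemic-artery
    vessel_class: artery
    proximal_node: n-aorta
    distal_node: n-systemic
    length_cm: 45
    radius_mm: 9.0
    wall_mm: 1.0
    stiffness_MPa: 0.15           # effective (whole-tree storage), not tissue
    adapting: false
  - id: subclavian-artery
    vessel_class: artery
    proximal_node: n-aorta
    distal_node: n-axilla
    length_cm: 12
    radius_mm: 4.0
    wall_mm: 0.75
    stiffness_MPa: 0.4
    adapting: false
  - id: axillary-artery
    vessel_class: artery
    proximal_node: n-axilla
    distal_node: n-arm-prox
    length_cm: 10
    radius_mm: 3.0
    wall_mm: 0.65
    stiffness_MPa: 0.4
    adapting: false
  - id: brachial-artery-mid       # DUS site: brachial artery, middle arm
    vessel_class: artery
    proximal_node: n-arm-prox
    distal_node: n-arm-mid
    length_cm: 10
    radius_mm: 2.2                # brachial lumen diameter ~4-4.5 mm
    wall_mm: 0.55
    stiffness_MPa: 0.45
    adapting: true
  - id: brachial-artery-elbow     # DUS site: brachial artery at the elbow
    vessel_class: artery
    proximal_node: n-arm-mid
    distal_node: n-elbow-a
    length_cm: 10
    radius_mm: 2.1
    wall_mm: 0.5
    stiffness_MPa: 0.45
    adapting: true
  - id: radial-artery-mid         # DUS site: radial artery, mid forearm
    vessel_class: artery
    proximal_node: n-elbow-a
    distal_node: n-forearm-rad
    length_cm: 12
    radius_mm: 1.4                # radial diameter ~2.4-3 mm
    wall_mm: 0.35
    stiffness_MPa: 0.8            # muscular artery, stiffer than elastic
    adapting: true
  - id: radial-artery-distal      # DUS site: radial artery, distal (wrist)
    vessel_class: artery
    proximal_node: n-forearm-rad
    distal_node: n-wrist-rad
    length_cm: 11
    radius_mm: 1.25
    wall_mm: 0.33
    stiffness_MPa: 0.8
    adapting: true
  - id: ulnar-artery-mid          # DUS site: ulnar artery, mid forearm
    vessel_class: artery
    proximal_node: n-elbow-a
    distal_node: n-forearm-uln
    length_cm: 12
    radius_mm: 1.5
    wall_mm: 0.35
    stiffness_MPa: 0.8
    adapting: true
  - id: ulnar-artery-distal       # DUS site: ulnar artery, distal
    vessel_class: artery
    proximal_node: n-forearm-uln
    distal_node: n-wrist-uln
    length_cm: 11
    radius_mm: 1.35
    wall_mm: 0.33
    stiffness_MPa: 0.8
    adapting: true
  - id: palmar-arch               # radial-ulnar communication at the hand
    vessel_class: artery
    proximal_node: n-wrist-rad
    distal_node: n-wrist-uln
    length_cm: 5
    radius_mm: 0.9
    wall_mm: 0.25
    stiffness_MPa: 0.8
    adapting: false

  # ---- veins --------------------------------------------------------------
  - id: cephalic-vein-wrist       # DUS station: cephalic vein at the wrist
    vessel_class: vein
    proximal_node: n-wrist-v
    distal_node: n-forearm-v
    length_cm: 12
    radius_mm: 1.25               # cephalic diameter ~2.5 mm under cuff
    wall_mm: 0.3
    stiffness_MPa: 0.3
    adapting: true
  - id: cephalic-vein-forearm     # DUS station: cephalic vein, forearm
    vessel_class: vein
    proximal_node: n-forearm-v
    distal_node: n-elbow-v
    length_cm: 13
    radius_mm: 1.5
    wall_mm: 0.3
    stiffness_MPa: 0.3
    adapting: true
  - id: cubital-vein              # median cubital, cephalic-basilic bridge
    vessel_class: vein
    proximal_node: n-elbow-v
    distal_node: n-basilic-j
    length_cm: 5
    radius_mm: 1.8
    wall_mm: 0.3
    stiffness_MPa: 0.3
    adapting: true
  - id: basilic-vein
    vessel_class: vein
    proximal_node: n-basilic-j
    distal_node: n-axilla-v
    length_cm: 20
    radius_mm: 2.0
    wall_mm: 0.35
    stiffness_MPa: 0.3
    adapting: false
  - id: cephalic-vein-upper       # DUS station: cephalic vein, upper arm
    vessel_class: vein
    proximal_node: n-elbow-v
    distal_node: n-shoulder-v
    length_cm: 22
    radius_mm: 1.7
    wall_mm: 0.3
    stiffness_MPa: 0.3
    adapting: true
  - id: cephalic-arch             # DUS station: cephalic arch
    vessel_class: vein
    proximal_node: n-shoulder-v
    distal_node: n-subclavian-v
    length_cm: 4
    radius_mm: 1.8
    wall_mm: 0.3
    stiffness_MPa: 0.3
    adapting: true
  - id: axillary-vein
    vessel_class: vein
    proximal_node: n-axilla-v
    distal_node: n-subclavian-v
    length_cm: 8
    radius_mm: 2.5
    wall_mm: 0.4
    stiffness_MPa: 0.3
    adapting: false
  - id: subclavian-vein           # DUS station: subclavian vein
    vessel_class: vein
    proximal_node: n-subclavian-v
    distal_node: n-central-v
    length_cm: 10
    radius_mm: 4.0
    wall_mm: 0.45
    stiffness_MPa: 0.3
    adapting: false

terminals:
  # lumped remainder of the systemic circulation: ~5.6 L/min at ~93 mmHg
  - name: systemic-bed
    node: n-systemic
    resistance_mmHg_min_ml: 0.017
  # upper-arm muscle/skin side branches: ~20 mL/min at 93 mmHg
  - name: upper-arm-bed
    node: n-arm-mid
    resistance_mmHg_min_ml: 4.6
  # forearm side branches: ~25 mL/min each
  - name: forearm-radial-bed
    node: n-forearm-rad
    resistance_mmHg_min_ml: 3.7
  - name: forearm-ulnar-bed
    node: n-forearm-uln
    resistance_mmHg_min_ml: 3.7
  # hand beds: ~30 mL/min each
  - name: hand-radial-bed
    node: n-wrist-rad
    resistance_mmHg_min_ml: 3.1
  - name: hand-ulnar-bed
    node: n-wrist-uln
    resistance_mmHg_min_ml: 3.1
  # peripheral venous drainage of the hand into the cephalic origin; carries
  # negligible flow pre-operatively (the microcirculation is not resolved)
  - name: hand-venous-bed
    node: n-wrist-v
    resistance_mmHg_min_ml: 50
  # central venous outflow to the right atrium (reference pressure 0 mmHg)
  - name: central-venous
    node: n-central-v
    resistance_mmHg_min_ml: 0.004
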