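category,term,mode
Myalgia,myalgia,EXACT_TERM
Rhabdomyolysis,rhabdomyolysis,EXACT_TERM
Myositis,myositis,EXACT_TERM
Myopathy,myopathy,EXACT_TERM
Joints and Tendons,arthralgia,EXACT_TERM
Joints and Tendons,tendonitis,EXACT_TERM
Joints and Tendons,tendon rupture,EXACT_TERM
Joints and Tendons,tendon disorder,EXACT_TERM
Joints and Tendons,joint stiffness,EXACT_TERM
Joints and Tendons,joint swelling,EXACT_TERM
Muscle Atrophy and Injury,muscle atrophy,EXACT_TERM
Muscle Atrophy and Injury,muscle injury,EXACT_TERM
Muscle Atrophy and Injury,muscle necrosis,EXACT_TERM
Muscle Atrophy and Injury,muscle rupture,EXACT_TERM
Muscle Coordination and Weakness,muscular weakness,EXACT_TERM
Muscle Coordination and Weakness,muscle spasms,EXACT_TERM
Muscle Coordination and Weakness,coordination abnormal,EXACT_TERM
Muscle Coordination and Weakness,gait disturbance,EXACT_TERM
Muscle Coordination and Weakness,muscle twitching,EXACT_TERM
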