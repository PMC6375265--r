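section,kind,radius_mm,angle_deg,parent,thickness_mm,remark,upstream_angle_deg,stress_radius_mm
CCA-1,straight,8.5,,,19-39,Wider,,
CCA-2,straight,8.5,,CCA-1,50-79,Wider,,
CCA-3,bifurcation,10,,CCA-2,7-15,Bif. ECA/ICA,,
ECA-1,bend,5.0,20,CCA-3,1.0-2.5,Bend/Bif.,,
ECA-2,bifurcation,4.5,,ECA-1,2-5,Wider,,
ECA-3,bend,4.0,52,ECA-2,1.5-8,Bend,51,
ECA-4,bifurcation,2.5,,ECA-3,1-3,Narrower,,
ECA-5,bend,2.0,60,ECA-4,2-11,Bend,,
ECA-6,straight,2.0,,ECA-5,NIL,Straight,,
ECA-7,bend,2.0,30,ECA-6,2-10,Bend,,
ECA-8,bifurcation,1.5,,ECA-7,2-8,Bif.,,
ECA-9,bifurcation,1.5,,ECA-8,1.5-2.5,Bif.,,
ICA-1,bend,5.5,28,CCA-3,2-7,Bend,,
ICA-2,bend,5.0,48,ICA-1,2-15,Bend,,5.5
ICA-3,straight,5.0,,ICA-2,22,Straight,,
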