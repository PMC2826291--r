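"","Event_Normal","Event_Report","Event_Hypothetical","Event_Info"
"Event_Normal",436,3,2,12
"Event_Report",8,242,0,0
"Event_Hypothetical",1,0,36,13
"Event_Info",15,0,2,138
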