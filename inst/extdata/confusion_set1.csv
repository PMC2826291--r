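"","Event_Normal","Event_Report","Event_Hypothetical","Event_Info"
"Event_Normal",543,6,11,27
"Event_Report",17,247,0,0
"Event_Hypothetical",6,0,51,6
"Event_Info",13,0,1,158
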