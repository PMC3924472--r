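id,name,area,deadline_bucket,requested_by
ac1,finish maths homework,academic,today,mother
ac2,study for history exam,academic,within_week,nobody
ac3,hand in overdue essay,academic,overdue,someone_else
ac4,read optional book chapter,academic,none,nobody
pe1,tidy bedroom,personal,within_week,mother
pe2,pack sports kit,personal,today,nobody
pe3,renew bus pass,personal,later,father
pe4,sort old clothes,personal,none,nobody
fa1,help with grocery shopping,family,today,father
fa2,visit grandparents,family,within_week,mother
fa3,walk the dog,family,today,nobody
fa4,help paint the fence,family,later,father
le1,football practice,leisure,today,nobody
le2,finish video game level,leisure,none,nobody
le3,cinema with friends,leisure,within_week,someone_else
le4,plan weekend bike ride,leisure,later,nobody
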