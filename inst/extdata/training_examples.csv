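area,deadline_bucket,requested_by,label
academic,overdue,father,priority
academic,overdue,mother,priority
academic,overdue,someone_else,priority
academic,overdue,nobody,priority
academic,today,father,priority
academic,today,mother,priority
academic,today,someone_else,priority
academic,today,nobody,priority
academic,within_week,father,priority
academic,within_week,mother,priority
academic,within_week,someone_else,non_priority
academic,within_week,nobody,non_priority
academic,later,father,non_priority
academic,later,mother,non_priority
academic,later,someone_else,non_priority
academic,later,nobody,non_priority
academic,none,father,non_priority
academic,none,mother,non_priority
academic,none,someone_else,non_priority
academic,none,nobody,non_priority
family,overdue,father,priority
family,overdue,mother,priority
family,overdue,someone_else,priority
family,overdue,nobody,priority
family,today,father,priority
family,today,mother,priority
family,today,someone_else,priority
family,today,nobody,priority
family,within_week,father,priority
family,within_week,mother,priority
family,within_week,someone_else,non_priority
family,within_week,nobody,non_priority
family,later,father,non_priority
family,later,mother,non_priority
family,later,someone_else,non_priority
family,later,nobody,non_priority
family,none,father,non_priority
family,none,mother,non_priority
family,none,someone_else,non_priority
family,none,nobody,non_priority
leisure,overdue,father,priority
leisure,overdue,mother,priority
leisure,overdue,someone_else,priority
leisure,overdue,nobody,priority
leisure,today,father,priority
leisure,today,mother,priority
leisure,today,someone_else,priority
leisure,today,nobody,priority
leisure,within_week,father,priority
leisure,within_week,mother,priority
leisure,within_week,someone_else,non_priority
leisure,within_week,nobody,non_priority
leisure,later,father,non_priority
leisure,later,mother,non_priority
leisure,later,someone_else,non_priority
leisure,later,nobody,non_priority
leisure,none,father,non_priority
leisure,none,mother,non_priority
leisure,none,someone_else,non_priority
leisure,none,nobody,non_priority
personal,overdue,father,priority
personal,overdue,mother,priority
personal,overdue,someone_else,priority
personal,overdue,nobody,priority
personal,today,father,priority
personal,today,mother,priority
personal,today,someone_else,priority
personal,today,nobody,priority
personal,within_week,father,priority
personal,within_week,mother,priority
personal,within_week,someone_else,non_priority
personal,within_week,nobody,non_priority
personal,later,father,non_priority
personal,later,mother,non_priority
personal,later,someone_else,non_priority
personal,later,nobody,non_priority
personal,none,father,non_priority
personal,none,mother,non_priority
personal,none,someone_else,non_priority
personal,none,nobody,non_priority
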